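---
title: "Methods: recurrent gene loss, from disruption calls to selection intensity"
author: "geneloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent gene loss, from disruption calls to selection intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

GBA3 encodes a cytosolic beta-glucosidase that hydrolyses dietary plant
beta-glycosides. In humans it is a *polymorphic pseudogene*: a truncating
allele (rs358231, c.1368 T>A, p.Y456X) segregates at substantial frequency,
so functional and inactivated alleles coexist. Across mammals the same gene
has been silenced repeatedly — in cetaceans, pinnipeds, several rodents and
bats, the elephant and the manatee — apparently wherever diet stopped
exercising it. This package turns that analysis into reusable, tested code:

1. **annotation** — find ORF-disrupting mutations (premature stops,
   frameshift indels, splice-site losses) in genomic sequence against a
   reference gene model, and validate them with read-evidence summaries;
2. **loss mapping** — cluster identical disruptions across species and count
   the minimum number of independent inactivation events on a species tree;
3. **selection** — branch-model codon likelihoods (dN/dS classes per clade
   or stem branch), a nested likelihood-ratio ladder, and a simplified
   RELAX-style selection-intensity test;
4. **population statistics** — allele/homozygote frequencies, Hardy-Weinberg
   tests, damaging-variant filtering, loss-of-function density, o/e
   constraint with a LOEUF-style bound, windowed diversity with Tajima's D,
   and a JZS Bayes-factor one-sample test;
5. **simulation** — generators with known truth for every stage, so the
   whole pipeline is testable without any external database.

Coordinates are 0-based half-open internally and 1-based in every report and
HGVS-style label; the reference CDS excludes the terminal stop, so a 1407 bp
ORF encodes 469 residues and c.1368 falls in codon 456.

# Annotation: manual curation made algorithmic

The original annotation of candidate pseudogenes was manual (exon maps
inspected in an alignment viewer). `map_exons()` replaces that with a
deterministic, auditable procedure:

* each reference exon is located by **local alignment** (match +2, mismatch
  −3, gap open −8, gap extend −2) within the slice region following the
  previous exon, then re-aligned **pattern-globally** inside a padded window
  so that indels near exon boundaries are not silently clipped;
* an exon is accepted when identity ≥ 0.6 over ≥ 60% of its length,
  otherwise it is reported as missing data;
* splice boundaries may shift by up to ±12 bp towards dialect conformity,
  but only when the shifted bases are compatible with the reference — a
  genuinely mutated GT/GC donor or AG acceptor is therefore reported, not
  explained away. Donor dialects are declared per intron (GBA3's intron 2
  donor is GC, and the model records that, so a GC donor is not a loss).

`detect_disruptions()` walks the aligned columns once, tracking the reading
frame through indels. Premature stops are emitted for every in-frame stop
upstream of the reference terminus *in the target frame*, so an upstream
frameshift changes which codons downstream read as stops exactly as a
re-translation of the edited CDS predicts (this equivalence is a test).
Unobserved reference positions (missing exons, masked blocks, codons with
ambiguity characters) enter the reconstruction as `N` and are skipped during
stop detection — missing data never creates an event, and the frame is
assumed conserved across unobserved blocks, which is the conservative
reading when no sequence is available. Stop motifs are reported as the
preceding residues plus `X`; the default motif length in events is 4
(`DSLFX`), while the standalone `stop_context()` helper defaults to 3 —
published figures use both conventions, and we kept each where it appears.

`validate_events()` encodes the validation rule: *fixed* needs at least two
independent projects each showing `min_reads` disrupted reads with no intact
read anywhere; *polymorphic* needs one project showing both alleles (or
projects fixed for different alleles); anything thinner stays
*unvalidated*. The per-allele read threshold defaults to 3 — the source
procedure names no number, and 3 reads per allele per project is the
smallest count a curator would normally accept as seeing an allele rather
than an error. `call_status()` then maps events to
`coding` / `pseudogene` / `polymorphic_pseudogene` / `unresolved`; in-frame
indels are non-disrupting, and terminal stop-codon losses are out of scope
(the one database annotation of that kind in the source material is
mislabeled).

# Counting independent losses

Events are counted from **shared-disruption components**, not from plain
presence/absence (Dollo) parsimony: inactivated tips are joined when they
carry an identical disruption (same kind, same homologous CDS position,
same allele — stop codon identity, or indel length and string), and each
connected component is one event placed on the edge above its members'
MRCA. Dollo counting would merge adjacent lineages inactivated by distinct
mutations (elephant and manatee are sisters in the tree, each with private
stops) and is available via `method = "dollo"` only for comparison.
Polymorphic pseudogenes (red fox, African wild dog, human) are excluded by
default because an allele still segregating marks a loss in progress, not a
completed lineage event. A coding tip inside an event's clade, or a
non-monophyletic cluster, is reported as a warning rather than an error —
both patterns occur in real data through incomplete lineage sorting or
homoplasy.

On the packaged fixture this yields **nine** independent losses: the
cetacean ancestor (two stop clusters conserved across all seven sampled
cetaceans), Phocidae (a shared 13-nt exon-3 deletion), Otariidae (a shared
exon-3 stop), the walrus (three private frameshifts), one rodent event
(stop clusters shared by mouse and both mole-rats), the vampire bat, the
two flying foxes (a shared exon-5 stop), the elephant and the manatee.
Where the published material shows a motif but not the underlying codon
(the otariid and cetacean exon-3 stops share the DSLF context), the fixture
records distinct stop alleles so that the clusters remain what the source
treats them as: independent. The fixture encodes only species named in the
main text and figures; species lists confined to supplementary tables are
represented by typical members, and the packaged per-cell values that the
source does not print (exact positions, alleles, sparse frequency-table
cells, PolyPhen/SIFT scores of variants that passed the damaging filter)
are synthetic reconstructions — documented as such — so only
architecture-level counts (the nine events, the 18 vs 5 damaging variants,
the published frequencies of rs358231) are asserted against it.

# Branch models and the nested ladder

The codon model is the standard 61-state reversible chain: rate
`i -> j = pi_j * kappa^[transition] * omega^[nonsynonymous]` for
single-nucleotide changes, zero otherwise, each omega class scaled to mean
rate 1 at stationarity so branch lengths are expected substitutions per
codon. Likelihoods come from Felsenstein pruning over compressed site
patterns with per-node rescaling; transition matrices use the spectral
decomposition of the symmetrised generator. Gaps and ambiguous codons are
missing data. Equilibrium frequencies default to **F3x4** (the common
default of codon-model software; the source does not state its choice),
with F1x4 and F61 selectable; fits hold frequencies at their empirical
values rather than estimating them.

`fit_branch_model()` maximises over kappa, one omega per class and
(optionally) all branch lengths, by bounded quasi-Newton in log space
(omega in [1e-4, 99], kappa in [0.01, 100]) with fixed-seed restarts; a fit
that exhausts its restarts is returned flagged, never silently. Branch
lengths are co-estimated by default; the ladder drivers fix them at the
one-ratio estimates for speed, an option the model class makes explicit.

The 14-model ladder (A..N) ships as a machine-readable YAML: one background
ratio plus foreground groups over seven clade labels and two stem branches.
Nestedness is partition refinement on the edge-class maps, which reproduces
exactly the comparison set of the published table (K is nested in L, M and
N; M in N; L and M are not nested). `run_ladder()` fits all models and
selects the most complex model that significantly rejects every simpler
nested model while not being rejected from above. The chi-square arithmetic
(`LRT = 2(lnL_1 − lnL_0)`, df = parameter difference) reproduces the
published p-values at two decimals from the published statistics.

Calibration is asserted per comparison: with data simulated under the
one-ratio model, each nested test rejects the null at the nominal 5% rate,
i.e. model A is retained in about 95% of the individual ladder tests. The
family-wise retention of A across all thirteen simultaneous comparisons is
necessarily lower (the ladder applies no multiplicity correction, as in the
source analysis), so calibration is a per-test property, and the suite
measures it that way.

# Selection intensity (RELAX-style)

`relax_test()` draws site omegas from three estimated background categories
`(omega_i, weight_i)` and raises them to the power K on the test branches;
the null fixes K = 1, the alternative frees it, and a df-1 LRT decides.
K < 1 is relaxation, K > 1 intensification. This is a deliberate
simplification of the published test's machinery (three categories, no
synonymous-rate variation), reproducing its logic rather than any specific
software's numbers — the published cetacean result (K = 0.06, p = 0.003 on
real alignments) is therefore a qualitative reference, and the suite
verifies the test's type-I error and its power to recover strong relaxation
from simulated truth instead. Per-category site likelihoods are memoised
across optimizer steps, which makes the mixture fits cheap.

# Population statistics

All frequency arithmetic is exact: allele frequency `(n_Aa + 2 n_aa)/2N`,
homozygous-minor frequency `n_aa/N`. The HWE test defaults to the df-1
chi-square without continuity correction (the online calculator the source
cites does not state its method); a conditional exact test and the Yates
correction are selectable. Damaging missense variants are those with
PolyPhen in [0.7, 1] **and** SIFT in [0, 0.3], bounds inclusive since the
source writes the ranges without strictness; ORF-disrupting consequences
pass regardless of scores. Constraint is `oe = observed/expected` with a
LOEUF-style bound: the upper end of the two-sided 90% Poisson confidence
interval for the rate multiplier, i.e. the `lambda` with
`P(X <= observed | lambda * expected) = 0.05`. The published 14 observed vs
27.3 expected gives oe 0.51 and a bound of 0.8; since gnomAD's full
procedure differs in detail, agreement is asserted at one decimal only.
Diversity scans report S, per-site pi and Tajima's D with the standard
constants per 100 kb window (D is undefined at S = 0 and reported missing).
The Bayes-factor one-sample test is the Jeffreys-Zellner-Siow integral
(Cauchy prior on the standardised effect, scale 0.707 — the default of the
desktop statistics tool the source used) computed by adaptive quadrature
and checked against an independent grid quadrature. Superpopulation means
are unweighted over member populations, the source's weighting being
unstated.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions:

* `sim_codon_alignment()` evolves codons by the exact transition kernel of
  the branch model — root from pi, per-branch `exp(tQ)` — so stops can
  never arise and simulate-refit recovery is a clean test of the estimator;
* `sim_relax_alignment()` adds the site-category mixture with `omega^K` on
  test branches;
* `sim_gene_locus()` plants stops, indels, splice edits and masked blocks
  into a genomic slice built from the reference exons with random introns
  carrying the declared splice dialects;
* `sim_read_evidence()` draws binomial read counts per project;
* `sim_genotypes()` draws genotype triples under HWE or inbreeding `f`;
* `sim_coalescent_haplotypes()` is the standard neutral Kingman coalescent
  with infinite-sites mutations (time in units of 2N, mutation rate
  `theta/2` per lineage).

A single run seed fans out to per-component substreams
(`substream_seed()`), so adding one generator call never perturbs another's
stream, and every generator returns its truth table. What the generators do
**not** emulate: sequencing error beyond binomial sampling, alignment
uncertainty, paralogous mapping, recombination, demography or selection in
the coalescent, and synonymous-rate variation. Passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
robustness to every artefact of real genome data.

# Numerical choices and problem sizes

Tolerances: pruning vs brute-force marginalisation at 1e-8; rate-matrix
stationarity at 1e-10; nested fits may trail by at most 1e-6 log units.
Optimiser: L-BFGS-B on log-transformed parameters, convergence `factr` 1e7
(5e7 for the mixture; the repeated-replicate calibration studies use 5e8,
which still resolves log-likelihoods far below the resolution an LRT
needs), up to 300-400 iterations, restarts seeded from the run seed. Degenerate inputs: monomorphic genotype panels return p = 1 from
the HWE test; an alignment with no nonsynonymous variation drives omega to
its lower bound rather than an error; S = 0 windows report missing D;
likelihood underflow is prevented by per-node rescaling.

The simulation studies run at sizes chosen to make their statistical
targets decisive while keeping a full check of the package routine on a
laptop: omega recovery at 8 taxa x 2000 codons (the regime where the
estimator's relative error is safely under 10%), ladder calibration at 50
replicates of 200 codons on a 12-tip labelled tree, selection-intensity
calibration at 60 replicates of 200 codons on an 8-tip tree with power
measured at 1000 codons, 100 planted loci for detection, 500 neutral
coalescent replicates and 500 genotype panels for the popgen calibrations.
Recovery tests hand the generator's true equilibrium frequencies to the
fitter (the truth table is part of the simulated scenario); analyses of
unknown data estimate them from the alignment.

# Known limitations

* The exon mapper assumes the exons appear in reference order on the slice;
  rearranged or duplicated loci are out of scope, as is paralog
  discrimination.
* Frame conservation across missing blocks is an assumption, so a
  frameshift hidden entirely inside missing data is invisible — mirroring
  the source's treatment of low-coverage regions.
* The event counter trusts the clustering: identical convergent mutations
  in distant lineages merge into one event with a homoplasy warning rather
  than splitting automatically.
* The selection-intensity test is a simplified reimplementation; its
  numbers are comparable across runs of this package, not across software.
* Printed log-likelihoods are not available for the published ladder, so
  only the LRT arithmetic and p-values are reproduced exactly; the omega
  regime is validated by simulate-refit recovery instead.
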