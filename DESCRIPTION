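Package: geneloss
Title: Recurrent Gene Loss: Pseudogene Annotation, Loss-Event Counting,
    Branch-Model Selection and Population Loss-of-Function Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recurrent pseudogenization of a protein-coding
    gene across a mammalian phylogeny and within human populations, built
    around the cytosolic beta-glucosidase gene GBA3 as the worked case.
    Provides reference-guided exon mapping and ORF-disruption detection
    (premature stops, frameshift indels, splice-site loss) with read-evidence
    validation; clustering of identical disruptions across species and
    minimum independent loss-event counting on a labelled species tree;
    branch-model codon substitution likelihoods (dN/dS classes per clade or
    branch) with a nested likelihood-ratio-test model ladder and a
    selection-intensity (RELAX-style K) test; and population-level
    loss-of-function statistics (allele and homozygote frequencies,
    Hardy-Weinberg tests, damaging-variant filtering, LoF density,
    observed/expected constraint with a LOEUF-style Poisson bound, windowed
    nucleotide diversity and Tajima's D, and a JZS Bayes-factor one-sample
    test). Synthetic-data generators with known truth make every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
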