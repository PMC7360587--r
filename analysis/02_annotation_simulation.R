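#!/usr/bin/env Rscript
# Annotation pipeline on synthetic loci: plant ORF disruptions in a 5-exon
# reference, rebuild genomic slices with introns, and run exon mapping,
# disruption detection, read-evidence validation and status calling.
#
# Finding: on clean loci the pipeline calls `coding`; planted stops,
# frameshift indels and splice losses are recovered exactly, and the
# validation lattice (fixed / polymorphic / unvalidated) maps onto
# pseudogene / polymorphic_pseudogene / unresolved as designed.

library(geneloss)

dir.create("results/annotation", recursive = TRUE, showWarnings = FALSE)
model <- make_demo_gene_model()

scenarios <- list(
  cetacean_like = list(plan = list(list(kind = "stop", codon = 244L),
                                   list(kind = "stop", codon = 264L)),
                       freq = 1, projects = 3),
  phocid_like = list(plan = list(list(kind = "deletion", at = 640L,
                                      len = 13L)),
                     freq = 1, projects = 2),
  fox_like = list(plan = list(list(kind = "deletion", at = 615L, len = 1L)),
                  freq = 0.5, projects = 2),
  colobus_like = list(plan = list(list(kind = "deletion", at = 700L,
                                       len = 2L)),
                      freq = 1, projects = 0),
  intact = list(plan = list(), freq = 1, projects = 2)
)

rows <- list()
for (nm in names(scenarios)) {
  sc <- scenarios[[nm]]
  sim <- sim_gene_locus(model, plan = sc$plan, seed = 42L)
  ev <- detect_disruptions(map_exons(model, sim$genomic), model, species = nm)
  evd <- sim_read_evidence(ev, depth = 25L, disrupted_allele_freq = sc$freq,
                           n_projects = sc$projects, seed = 7L)
  ev <- validate_events(ev, evd)
  call <- call_status(ev, coverage_complete = TRUE, species = nm,
                      gene_id = model$gene_id)
  cat(sprintf("%-14s -> %-24s (%d events)\n", nm, call$status, nrow(ev)))
  if (nrow(ev)) rows[[nm]] <- cbind(scenario = nm, ev)
}
events <- do.call(rbind, rows)
write.table(events, "results/annotation/planted_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Events written to results/annotation/planted_events.tsv\n")
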