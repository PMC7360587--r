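demo_model <- make_demo_gene_model()

test_that("exons planted with identity are recovered at exact coordinates", {
  sim <- sim_gene_locus(demo_model, plan = list(), intron_len = 500L, seed = 5L)
  al <- map_exons(demo_model, sim$genomic)
  widths <- demo_model$exons[, 2] - demo_model$exons[, 1]
  exp_start <- cumsum(c(0L, head(widths, -1L) + 500L))
  for (i in seq_along(al)) {
    expect_false(al[[i]]$missing_data)
    expect_equal(al[[i]]$identity, 1)
    expect_equal(al[[i]]$tgt_interval, c(exp_start[i], exp_start[i] + widths[i]))
    expect_equal(al[[i]]$ref_span, c(1L, widths[i]))
  }
  expect_equal(vapply(al[-5], `[[`, character(1), "donor_obs"),
               demo_model$donor_dialect)
  expect_equal(vapply(al[-1], `[[`, character(1), "acceptor_obs"),
               rep("AG", 4))
  expect_equal(nrow(detect_disruptions(al, demo_model)), 0L)
})

test_that("alignment scores under 5% substitution noise match the DP oracle", {
  sim <- sim_gene_locus(demo_model, plan = list(), intron_len = 300L, seed = 9L)
  g <- sim$genomic
  set.seed(42)
  idx <- sample(nchar(g), round(0.05 * nchar(g)))
  gs <- strsplit(g, "")[[1]]
  gs[idx] <- vapply(gs[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  g2 <- paste(gs, collapse = "")
  al <- map_exons(demo_model, g2)
  widths <- demo_model$exons[, 2] - demo_model$exons[, 1]
  offs <- cumsum(c(0L, head(widths, -1L)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE)
  for (i in seq_along(al)) {
    a <- al[[i]]
    expect_false(a$missing_data)
    ref_ex <- substr(demo_model$cds_seq, offs[i] + 1L, offs[i] + widths[i])
    # oracle restricted to a window around the mapped interval
    win <- substr(g2, max(1L, a$tgt_interval[1] - 50L), a$tgt_interval[2] + 50L)
    pa <- Biostrings::pairwiseAlignment(ref_ex, win, type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 8, gapExtension = 2)
    expect_equal(Biostrings::score(pa), sw_local_score(ref_ex, win))
    # identity agrees with a recount over the returned alignment columns
    pc <- strsplit(a$ref_aligned, "")[[1]]
    sc <- strsplit(a$tgt_aligned, "")[[1]]
    both <- pc != "-" & sc != "-"
    expect_equal(a$identity, mean(pc[both] == sc[both]))
    expect_gt(a$identity, 0.85)
  }
})

test_that("declared GC donors and lost splice sites are told apart", {
  clean <- sim_gene_locus(demo_model, plan = list(), seed = 2L)
  al <- map_exons(demo_model, clean$genomic)
  expect_equal(al[[2]]$donor_obs, "GC")
  expect_equal(nrow(detect_disruptions(al, demo_model)), 0L)

  lost <- sim_gene_locus(demo_model, plan = list(
    list(kind = "splice", intron = 3, site = "donor", to = "AT"),
    list(kind = "splice", intron = 1, site = "acceptor", to = "AA")), seed = 2L)
  ev <- detect_disruptions(map_exons(demo_model, lost$genomic), demo_model)
  expect_setequal(ev$kind, "splice_loss")
  don <- ev[ev$splice_site == "donor", ]
  expect_equal(don$observed_site, "AT")
  expect_equal(don$exon_index, 3L)
  acc <- ev[ev$splice_site == "acceptor", ]
  expect_equal(acc$observed_site, "AA")
  expect_equal(acc$exon_index, 2L)
})

test_that("stops, frameshifts and in-frame indels are detected as planted", {
  ev <- detect_disruptions(map_exons(demo_model, sim_gene_locus(
    demo_model, plan = list(list(kind = "stop", codon = 244)),
    seed = 7L)$genomic), demo_model)
  expect_equal(ev$kind, "premature_stop")
  expect_equal(ev$cds_nt_pos, 730L)
  expect_equal(ev$codon_index, 244L)
  expect_equal(ev$stop_context, "DSLFX")
  expect_equal(ev$allele, "TAA")

  ev <- detect_disruptions(map_exons(demo_model, sim_gene_locus(
    demo_model, plan = list(list(kind = "deletion", at = 640, len = 13)),
    seed = 8L)$genomic), demo_model)
  del <- ev[ev$kind == "deletion", ]
  expect_equal(del$indel_len, 13L)
  expect_equal(del$exon_index, 3L)
  expect_true(del$frameshift)

  ev <- detect_disruptions(map_exons(demo_model, sim_gene_locus(
    demo_model, plan = list(list(kind = "deletion", at = 900, len = 3)),
    seed = 8L)$genomic), demo_model)
  expect_equal(ev$kind, "deletion")
  expect_false(ev$frameshift)
  expect_equal(ev$indel_len, 3L)
})

test_that("frame tracking through upstream indels matches re-translation", {
  plans <- list(
    list(list(kind = "deletion", at = 640, len = 13)),
    list(list(kind = "deletion", at = 300, len = 1)),
    list(list(kind = "insertion", at = 700, seq = "GG"),
         list(kind = "stop", codon = 400)),
    list(list(kind = "deletion", at = 100, len = 2),
         list(kind = "deletion", at = 800, len = 1))
  )
  for (p in plans) {
    sim <- sim_gene_locus(demo_model, plan = p, seed = 13L)
    ev <- detect_disruptions(map_exons(demo_model, sim$genomic), demo_model)
    got <- ev$allele[ev$kind == "premature_stop"]
    expect_equal(got, translate_stops_oracle(demo_model, p))
  }
})

test_that("stop_context truncates and sizes motifs as requested", {
  prot <- demo_model$protein_seq
  expect_equal(stop_context("AKPDR", 6, k = 3), "PDRX")
  expect_equal(stop_context(prot, 244, k = 4), "DSLFX")
  expect_equal(stop_context(prot, 2, k = 3),
               paste0(substr(prot, 1, 1), "X"))
  expect_error(stop_context(prot, 0, k = 3), "out of range")
  expect_error(stop_context(prot, 471, k = 3), "out of range")
})

test_that("read-evidence validation follows the two-project rule", {
  sim <- sim_gene_locus(demo_model,
                        plan = list(list(kind = "stop", codon = 244)), seed = 7L)
  ev <- detect_disruptions(map_exons(demo_model, sim$genomic), demo_model,
                           species = "test_sp")
  fixed <- validate_events(ev, sim_read_evidence(ev, 20, 1, 2, seed = 3L))
  expect_equal(fixed$validation, "validated_fixed")
  expect_equal(fixed$n_supporting_projects, 2L)

  mixed <- validate_events(ev, data.frame(
    project_id = "SRP001", species = "test_sp", event_key = event_key(ev),
    reads_disrupted = 10L, reads_intact = 8L))
  expect_equal(mixed$validation, "validated_polymorphic")

  none <- validate_events(ev, sim_read_evidence(ev, 20, 1, 0, seed = 3L))
  expect_equal(none$validation, "unvalidated")

  one <- validate_events(ev, data.frame(
    project_id = "SRP001", species = "test_sp", event_key = event_key(ev),
    reads_disrupted = 15L, reads_intact = 0L))
  expect_equal(one$validation, "unvalidated")

  # discordant fixation across projects is polymorphism
  disc <- validate_events(ev, data.frame(
    project_id = c("SRP001", "SRP002"), species = "test_sp",
    event_key = rep(event_key(ev), 2),
    reads_disrupted = c(12L, 0L), reads_intact = c(0L, 9L)))
  expect_equal(disc$validation, "validated_polymorphic")

  expect_error(validate_events(ev, data.frame(
    project_id = "SRP001", species = "test_sp", event_key = "nope",
    reads_disrupted = 5L, reads_intact = 0L)), "unknown event key")
})

test_that("adding concordant evidence never demotes a validated event", {
  sim <- sim_gene_locus(demo_model,
                        plan = list(list(kind = "stop", codon = 300)), seed = 4L)
  ev <- detect_disruptions(map_exons(demo_model, sim$genomic), demo_model,
                           species = "sp")
  base <- sim_read_evidence(ev, 15, 1, 2, seed = 6L)
  expect_equal(validate_events(ev, base)$validation, "validated_fixed")
  for (extra_projects in 1:4) {
    more <- sim_read_evidence(ev, 15, 1, 2 + extra_projects, seed = 6L)
    expect_equal(validate_events(ev, more)$validation, "validated_fixed")
  }
})

test_that("status calls cover the whole validation lattice", {
  mk <- function(kind, validation, frameshift = FALSE) {
    data.frame(species = "sp", gene_id = "G", kind = kind, exon_index = 1L,
               cds_nt_pos = 10L, codon_index = 4L,
               indel_len = if (frameshift) 1L else 3L,
               frameshift = frameshift, splice_site = NA, observed_site = NA,
               stop_context = NA, allele = "TAA", cluster_id = NA,
               validation = validation, n_supporting_projects = 0L,
               stringsAsFactors = FALSE)
  }
  expect_equal(call_status(empty <- mk("premature_stop", "x")[0, ], TRUE,
                           species = "sp", gene_id = "G")$status, "coding")
  expect_equal(call_status(empty, FALSE, species = "sp",
                           gene_id = "G")$status, "unresolved")
  kinds <- c("premature_stop", "deletion", "splice_loss")
  vals <- c("validated_fixed", "validated_polymorphic", "unvalidated")
  for (k in kinds) for (v in vals) for (cov in c(TRUE, FALSE)) {
    ev <- mk(k, v, frameshift = k == "deletion")
    st <- call_status(ev, cov)$status
    expect_true(st %in% c("coding", "pseudogene", "polymorphic_pseudogene",
                          "unresolved"))
    if (v == "validated_fixed") expect_equal(st, "pseudogene")
    if (v == "validated_polymorphic") expect_equal(st, "polymorphic_pseudogene")
    if (v == "unvalidated") expect_equal(st, "unresolved")
  }
  # a non-disrupting in-frame deletion leaves the gene coding
  ev <- mk("deletion", "validated_fixed", frameshift = FALSE)
  expect_equal(call_status(ev, TRUE)$status, "coding")
  # fixed beats polymorphic when both are present
  both <- rbind(mk("premature_stop", "validated_fixed"),
                mk("splice_loss", "validated_polymorphic"))
  expect_equal(call_status(both, TRUE)$status, "pseudogene")
})
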