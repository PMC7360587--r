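pi_sim <- f3x4_freqs(c(0.28, 0.22, 0.26, 0.24))

test_that("generators are bitwise reproducible for a fixed seed", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,c:0.3);")
  spec <- branch_model_spec(tr, "A")
  params <- list(kappa = 2, omegas = 0.5, pi = pi_sim)
  s1 <- sim_codon_alignment(tr, spec, params, 40, seed = 9L)
  s2 <- sim_codon_alignment(tr, spec, params, 40, seed = 9L)
  expect_identical(s1$aln$codon, s2$aln$codon)
  expect_false(identical(
    s1$aln$codon, sim_codon_alignment(tr, spec, params, 40, seed = 10L)$aln$codon))

  m <- make_demo_gene_model()
  l1 <- sim_gene_locus(m, plan = list(list(kind = "stop", codon = 300)), seed = 4L)
  l2 <- sim_gene_locus(m, plan = list(list(kind = "stop", codon = 300)), seed = 4L)
  expect_identical(l1$genomic, l2$genomic)

  g1 <- sim_genotypes(c(p1 = 0.2, p2 = 0.4), 50, seed = 8L)
  g2 <- sim_genotypes(c(p1 = 0.2, p2 = 0.4), 50, seed = 8L)
  expect_identical(g1, g2)

  c1 <- sim_coalescent_haplotypes(10, 4, seed = 3L)
  c2 <- sim_coalescent_haplotypes(10, 4, seed = 3L)
  expect_identical(c1$haplotypes, c2$haplotypes)
})

test_that("zero branch lengths copy the root to every tip", {
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  s <- sim_codon_alignment(tr0, branch_model_spec(tr0, "A"),
                           list(kappa = 2, omegas = 1, pi = pi_sim), 50,
                           seed = 5L)
  expect_equal(s$aln$codon["a", ], s$aln$codon["b", ])
  expect_equal(s$aln$codon["a", ], s$aln$codon["c", ])
})

test_that("long simulations stay at the stationary codon distribution", {
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  s <- sim_codon_alignment(tr, branch_model_spec(tr, "A"),
                           list(kappa = 3, omegas = 0.4, pi = pi_sim),
                           50000, seed = 14L)
  emp <- tabulate(as.vector(s$aln$codon), nbins = 61) / (2 * 50000)
  tv <- 0.5 * sum(abs(emp - pi_sim))
  expect_lt(tv, 0.02)
})

test_that("neutral simulation yields the neutral nonsynonymous fraction", {
  # on a very short branch almost every difference is a single event, so the
  # nonsynonymous fraction among changes must match the rate-matrix flux
  tr <- ape::read.tree(text = "(a:0.005,b:0.005);")
  s <- sim_codon_alignment(tr, branch_model_spec(tr, "A"),
                           list(kappa = 1, omegas = 1, pi = pi_sim),
                           60000, seed = 15L)
  sense <- geneloss:::SENSE_CODONS
  a <- s$aln$codon["a", ]; b <- s$aln$codon["b", ]
  diffs <- which(a != b)
  ca <- sense[a[diffs]]; cb <- sense[b[diffs]]
  nd <- mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
               ca, cb)
  single <- nd == 1
  aa_of <- geneloss:::GENCODE_AA
  obs_frac <- mean(aa_of[ca[single]] != aa_of[cb[single]])
  Q <- codon_rate_matrix(1, 1, pi_sim)
  aa <- translate_cds(paste(sense, collapse = ""))
  aa <- strsplit(aa, "")[[1]]
  flux <- pi_sim * Q
  nonsyn <- outer(aa, aa, "!=")
  diag(nonsyn) <- FALSE
  exp_frac <- sum(flux[nonsyn & upper.tri(flux) | nonsyn & lower.tri(flux)]) /
    sum(flux[row(flux) != col(flux)])
  se <- sqrt(exp_frac * (1 - exp_frac) / sum(single))
  expect_lt(abs(obs_frac - exp_frac), 4 * se)
})

test_that("planted loci drive the annotation pipeline end to end", {
  m <- make_demo_gene_model()
  clean <- sim_gene_locus(m, plan = list(), seed = 2L)
  expect_equal(nrow(detect_disruptions(map_exons(m, clean$genomic), m)), 0L)

  del <- sim_gene_locus(m, plan = list(list(kind = "deletion", at = 640,
                                            len = 13)), seed = 3L)
  ev <- detect_disruptions(map_exons(m, del$genomic), m)
  d <- ev[ev$kind == "deletion", ]
  expect_equal(d$exon_index, del$truth$exon_index[1])
  expect_equal(d$indel_len, 13L)

  spl <- sim_gene_locus(m, plan = list(list(kind = "splice", intron = 2,
                                            site = "donor", to = "AT")),
                        seed = 3L)
  ev2 <- detect_disruptions(map_exons(m, spl$genomic), m)
  expect_equal(ev2$kind, "splice_loss")
  expect_equal(ev2$splice_site, "donor")
  expect_equal(ev2$exon_index, 2L)

  expect_error(sim_gene_locus(m, plan = list(list(kind = "deletion",
                                                  at = 1500, len = 5))),
               "outside CDS")
})

test_that("read-evidence generation hits the expected validation outcomes", {
  m <- make_demo_gene_model()
  sim <- sim_gene_locus(m, plan = list(list(kind = "stop", codon = 244)),
                        seed = 7L)
  ev <- detect_disruptions(map_exons(m, sim$genomic), m, species = "sp")

  fixed <- validate_events(ev, sim_read_evidence(ev, 20, 1, 2, seed = 1L))
  expect_equal(fixed$validation, "validated_fixed")

  # freq 0.5 at depth 20: both alleles clear min_reads with prob > 0.99
  poly_ok <- vapply(1:30, function(s) {
    e <- sim_read_evidence(ev, 20, 0.5, 1, seed = s)
    validate_events(ev, e)$validation == "validated_polymorphic"
  }, logical(1))
  expect_gte(mean(poly_ok), 0.9)

  none <- validate_events(ev, sim_read_evidence(ev, 20, 1, 0, seed = 1L))
  expect_equal(none$validation, "unvalidated")
  expect_error(sim_read_evidence(ev, 20, 1.2, 2), "\\[0, 1\\]")
})

test_that("genotype panels follow the inbreeding model", {
  mono <- sim_genotypes(c(p = 0), 100, seed = 2L)
  expect_equal(mono$n_AA, 100L)
  expect_error(sim_genotypes(c(p = 1.4), 10), "\\[0, 1\\]")

  # f = 0.5 heterozygote deficit is detected with high power
  panels <- sim_genotypes(stats::setNames(rep(0.2, 200), paste0("p", 1:200)),
                          n_per_pop = 500, inbreeding_f = 0.5, seed = 9L)
  rej <- vapply(seq_len(nrow(panels)), function(i) {
    hwe_test(unlist(panels[i, c("n_AA", "n_Aa", "n_aa")])) < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("the coalescent matches Watterson and pairwise expectations", {
  expect_error(sim_coalescent_haplotypes(1, 5), "at least 2")
  theta <- 5; n <- 20
  a1 <- sum(1 / (1:(n - 1)))
  reps <- lapply(1:400, function(s) sim_coalescent_haplotypes(n, theta, seed = s))
  S <- vapply(reps, function(r) ncol(r$haplotypes), numeric(1))
  expect_lt(abs(mean(S) - theta * a1) / (theta * a1), 0.05 + 3 * sd(S) /
              sqrt(length(S)) / (theta * a1))
  pi_hat <- vapply(reps[1:200], function(r) {
    h <- r$haplotypes
    d <- colSums(h)
    sum(d * (n - d)) / choose(n, 2)
  }, numeric(1))
  expect_lt(abs(mean(pi_hat) - theta) / theta, 0.1)

  # n = 2 pairwise TMRCA is exponential with mean 1 (units of 2N)
  tm <- vapply(1:500, function(s) sim_coalescent_haplotypes(2, 1, seed = s)$tmrca,
               numeric(1))
  expect_lt(abs(mean(tm) - 1), 0.15)
})
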