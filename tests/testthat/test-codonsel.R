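pi_test <- f3x4_freqs(c(0.3, 0.2, 0.3, 0.2))

test_that("alignment curation removes stops, gappy columns and listed codons", {
  raw <- c(s1 = "ATGCTTGGTTAA", s2 = "ATGCTCGGTTAG", s3 = "ATGCTTGGATGA")
  cur <- curate_alignment(raw)
  expect_equal(cur$n_codons, 3L)  # terminal stop column dropped

  raw2 <- c(s1 = "ATG---", s2 = "ATG---", s3 = "ATGCTT",
            s4 = "ATG---", s5 = "ATG---", s6 = "ATG---",
            s7 = "ATG---", s8 = "ATG---", s9 = "ATG---", s10 = "ATG---")
  cur2 <- curate_alignment(raw2)
  expect_equal(cur2$n_codons, 1L)  # 90% gap column removed

  raw3 <- c(s1 = "ATGTGACTT", s2 = "ATGCTCCTT")
  expect_error(curate_alignment(raw3), "stop codon remains.*s1")
  cur3 <- curate_alignment(raw3, disrupted_codons = list(s1 = 2L))
  expect_equal(cur3$n_codons, 3L)
  expect_true(is.na(cur3$codon["s1", 2]))
  expect_false(is.na(cur3$codon["s2", 2]))
})

test_that("the codon rate matrix is a scaled reversible generator", {
  for (par in list(c(2, 0.1), c(5, 1), c(1, 1.7))) {
    Q <- codon_rate_matrix(par[1], par[2], pi_test)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_lt(max(abs(pi_test %*% Q)), 1e-10)
    expect_equal(-sum(pi_test * diag(Q)), 1, tolerance = 1e-12)
    # detailed balance
    D <- diag(pi_test)
    expect_lt(max(abs(D %*% Q - t(D %*% Q))), 1e-14)
  }
})

test_that("pruning equals brute-force marginalisation on small trees", {
  # two taxa
  tr2 <- ape::read.tree(text = "(a:0.3,b:0.5);")
  spec2 <- branch_model_spec(tr2, "A")
  params <- list(kappa = 2.5, omegas = 0.4, pi = pi_test)
  sim2 <- sim_codon_alignment(tr2, spec2, params, 50, seed = 11L)
  Q <- codon_rate_matrix(2.5, 0.4, pi_test)
  P1 <- as.matrix(Matrix::expm(Q * 0.3))
  P2 <- as.matrix(Matrix::expm(Q * 0.5))
  bf <- sum(vapply(seq_len(50), function(k) {
    log(sum(pi_test * P1[, sim2$aln$codon["a", k]] *
              P2[, sim2$aln$codon["b", k]]))
  }, numeric(1)))
  expect_lt(abs(codon_loglik(sim2$aln, tr2, spec2, params) - bf), 1e-8)

  # three taxa, both internal states summed explicitly
  tr3 <- ape::read.tree(text = "((a:0.2,b:0.4):0.3,c:0.6);")
  spec3 <- branch_model_spec(tr3, "A")
  sim3 <- sim_codon_alignment(tr3, spec3, params, 20, seed = 12L)
  bf3 <- loglik3_oracle(sim3$aln, ta = 0.2, tb = 0.4, tn = 0.3, tc = 0.6,
                        kappa = 2.5, omega = 0.4, pi = pi_test)
  expect_lt(abs(codon_loglik(sim3$aln, tr3, spec3, params) - bf3), 1e-8)
})

test_that("identical sequences at zero branch lengths give the closed form", {
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  spec <- branch_model_spec(tr0, "A")
  params <- list(kappa = 2, omegas = 0.5, pi = pi_test)
  s0 <- sim_codon_alignment(tr0, spec, params, 30, seed = 3L)
  expect_equal(s0$aln$codon["a", ], s0$aln$codon["b", ])
  expect_equal(codon_loglik(s0$aln, tr0, spec, params),
               sum(log(pi_test[s0$aln$codon["a", ]])))
})

test_that("the likelihood is invariant under re-rooting", {
  set.seed(7)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.4))
  spec <- branch_model_spec(tr, "A")
  params <- list(kappa = 3, omegas = 0.6, pi = pi_test)
  sim <- sim_codon_alignment(tr, spec, params, 60, seed = 21L)
  base <- codon_loglik(sim$aln, tr, spec, params)
  un <- ape::unroot(tr)
  for (out in sample(tr$tip.label, 5)) {
    re <- ape::root(un, outgroup = out, resolve.root = TRUE)
    spec_re <- branch_model_spec(re, "A")
    expect_lt(abs(codon_loglik(sim$aln, re, spec_re, params) - base), 1e-8)
  }
})

test_that("LRT arithmetic and chi-square tails match published examples", {
  expect_equal(2 * 33.535, 67.07)
  expect_equal(round(chi2_sf(0.68, 1), 2), 0.41)
  expect_equal(round(chi2_sf(3.56, 1), 2), 0.06)
  expect_equal(round(chi2_sf(7.56, 3), 2), 0.06)
  expect_equal(chi2_sf(0, 1), 1)
  expect_equal(chi2_sf(0, 7), 1)
  expect_error(chi2_sf(1, 0), "df")

  f0 <- structure(list(spec = structure(list(model_id = "A",
                                             edge_class = c(1L, 1L),
                                             n_classes = 1L),
                                        class = "branch_model_spec"),
                       lnL = -100, n_free_params = 2L), class = "fit_result")
  f1 <- structure(list(spec = structure(list(model_id = "B",
                                             edge_class = c(1L, 2L),
                                             n_classes = 2L),
                                        class = "branch_model_spec"),
                       lnL = -100, n_free_params = 3L), class = "fit_result")
  r <- lrt(f0, f1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  f1$lnL <- -100 + 33.535
  expect_equal(lrt(f0, f1)$statistic, 67.07)
})

test_that("model nesting follows partition refinement as in the ladder", {
  stree <- make_demo_species_tree()
  ladder <- default_model_ladder()
  specs <- lapply(names(ladder$models), function(id) {
    branch_model_spec(stree, id, ladder$models[[id]])
  })
  names(specs) <- names(ladder$models)
  expect_equal(specs$A$n_classes, 1L)
  expect_equal(specs$N$n_classes, 5L)
  # every published comparison is properly nested
  for (k in seq_len(nrow(ladder$comparisons))) {
    expect_true(spec_is_nested(specs[[ladder$comparisons$null[k]]],
                               specs[[ladder$comparisons$alt[k]]]))
  }
  # the branch split L and the clade merge M are not nested either way
  expect_false(spec_is_nested(specs$L, specs$M))
  expect_false(spec_is_nested(specs$M, specs$L))
  expect_error(lrt(structure(list(spec = specs$L, lnL = 0,
                                  n_free_params = 4L), class = "fit_result"),
                   structure(list(spec = specs$M, lnL = 0,
                                  n_free_params = 5L), class = "fit_result")),
               "not nested")
})

test_that("fits respect nesting and hit the omega bound without signal", {
  stree <- make_demo_species_tree()
  specA <- branch_model_spec(stree, "A")
  specB <- branch_model_spec(stree, "B", list(fg1 = c("A1", "BranchA1")))
  for (seed in 1:3) {
    sim <- sim_codon_alignment(stree, specA,
                               list(kappa = 2, omegas = 0.3, pi = pi_test),
                               120, seed = seed)
    opts <- list(fix_branch_lengths = TRUE, n_restarts = 1, seed = 1,
                 pi = pi_test)
    fa <- fit_branch_model(sim$aln, stree, specA, opts)
    fb <- fit_branch_model(sim$aln, stree, specB, opts)
    expect_gte(fb$lnL, fa$lnL - 1e-6)
  }

  # purely synonymous divergence drives omega to its lower bound
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  base <- c("CTT", "GGT", "GCT", "CGT", "ACT", "TCT", "CCT", "GTT")
  s1 <- paste(rep(base, 15), collapse = "")
  syn <- c("CTC", "GGC", "GCC", "CGC", "ACC", "TCC", "CCC", "GTC")
  s2 <- paste(rep(c(syn[1:4], base[5:8]), 15), collapse = "")
  aln <- codon_alignment(c(a = s1, b = s2))
  fit <- fit_branch_model(aln, tr, branch_model_spec(tr, "A"),
                          list(n_restarts = 1, seed = 1))
  expect_lt(fit$params$omegas, 2e-4)
})

test_that("relabelling omega classes leaves the likelihood unchanged", {
  stree <- make_demo_species_tree()
  g1 <- list(fg1 = c("A1", "B1"), fg2 = "BranchB1", fg3 = "BranchA1")
  g2 <- list(fg1 = "BranchA1", fg2 = c("A1", "B1"), fg3 = "BranchB1")
  sM1 <- branch_model_spec(stree, "M", g1)
  sM2 <- branch_model_spec(stree, "Mperm", g2)
  sim <- sim_codon_alignment(stree, sM1,
                             list(kappa = 2, omegas = c(0.3, 1, 0.4, 1.5),
                                  pi = pi_test), 80, seed = 5L)
  w <- c(0.3, 1, 0.4, 1.5)
  l1 <- codon_loglik(sim$aln, stree, sM1,
                     list(kappa = 2, omegas = w, pi = pi_test))
  l2 <- codon_loglik(sim$aln, stree, sM2,
                     list(kappa = 2, omegas = w[c(1, 4, 2, 3)], pi = pi_test))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("a single-model ladder returns that model", {
  stree <- make_demo_species_tree()
  sim <- sim_codon_alignment(stree, branch_model_spec(stree, "A"),
                             list(kappa = 2, omegas = 0.3, pi = pi_test),
                             60, seed = 2L)
  res <- run_ladder(sim$aln, stree, ladder = list(models = list(A = list())),
                    opts = list(fix_branch_lengths = TRUE, n_restarts = 1,
                                pi = pi_test, seed = 1))
  expect_equal(res$best_id, "A")
})

test_that("relax test rejects degenerate test sets", {
  stree <- make_demo_species_tree()
  sim <- sim_codon_alignment(stree, branch_model_spec(stree, "A"),
                             list(kappa = 2, omegas = 0.3, pi = pi_test),
                             30, seed = 2L)
  expect_error(relax_test(sim$aln, stree, integer(0)), "empty")
  ne <- nrow(stree$phylo$edge)
  expect_error(relax_test(sim$aln, stree, seq_len(ne)), "proper subset")
})
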