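# Selection-intensity (RELAX-style) test: background site-omega categories,
# with test branches raising each category omega to the power K.

#' RELAX-style selection-intensity test
#'
#' Sites draw omega from three estimated background categories
#' `(omega_i, weight_i)`; on the test branches each category's omega becomes
#' `omega_i^K`. The null fixes the selection-intensity exponent `K = 1`, the
#' alternative estimates it freely; the two are compared with a df-1
#' likelihood-ratio test. `K < 1` with a significant p indicates relaxation
#' of selection on the test branches, `K > 1` intensification. This is a
#' deliberately simplified reimplementation of the test's logic (three
#' background categories, no synonymous-rate variation), not a replica of
#' any particular software's numbers.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [species_tree()] or `phylo` with branch lengths.
#' @param test_edges Edge rows (integers into `phylo$edge`) or clade/branch
#'   labels forming the test set; must be a non-empty proper subset of the
#'   edges.
#' @param alpha Significance threshold.
#' @param opts Options: `freq_method` ("F3x4"), `pi`, `blen`, `n_restarts`
#'   (2), `seed` (1), `maxit` (400). Branch lengths are held fixed at the
#'   tree's values.
#' @return A `relax_fit`: `omegas`, `weights`, `K`, `lnL_null`, `lnL_alt`,
#'   `statistic`, `p`, `direction`.
#' @export
relax_test <- function(aln, tree, test_edges, alpha = 0.05, opts = list()) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  rows <- if (is.character(test_edges)) label_edge_rows(tree, test_edges)
          else as.integer(test_edges)
  ne <- nrow(phy$edge)
  if (!length(rows)) stop("test edge set is empty")
  if (length(unique(rows)) >= ne) stop("test set must be a proper subset of the edges")
  if (any(rows < 1L | rows > ne)) stop("test edge index out of range")
  prep <- prep_pruning(aln, phy)
  pi <- opts$pi %||% codon_freqs(aln, opts$freq_method %||% "F3x4")
  blen <- opts$blen %||% phy$edge.length
  if (is.null(blen)) stop("no branch lengths available")
  spec2 <- list(model_id = "relax",
                edge_class = ifelse(seq_len(ne) %in% rows, 2L, 1L),
                n_classes = 2L)
  class(spec2) <- "branch_model_spec"
  n_cat <- 3L

  # memoise per-category site log-likelihoods: gradient steps that move only
  # the weights (or a single omega) then reuse the cached pruning results
  cat_cache <- new.env(parent = emptyenv())
  category_ll <- function(kappa, w_bg, K) {
    key <- sprintf("%.14g|%.14g|%.14g", kappa, w_bg, K)
    hit <- get0(key, envir = cat_cache)
    if (!is.null(hit)) return(hit)
    w_fg <- min(max(w_bg^K, 1e-6), 5e3)
    val <- loglik_from_prep(prep, spec2, kappa, c(w_bg, w_fg), pi, blen)
    if (length(ls(cat_cache)) > 300L) rm(list = ls(cat_cache), envir = cat_cache)
    assign(key, val, envir = cat_cache)
    val
  }
  mixture_ll <- function(kappa, omegas, weights, K) {
    per_cat <- vapply(seq_len(n_cat), function(c3) {
      category_ll(kappa, omegas[c3], K)
    }, numeric(prep$npat))
    m <- apply(per_cat, 1L, max)
    site <- m + log(as.vector(exp(per_cat - m) %*% weights))
    sum(prep$counts * site)
  }
  unpack <- function(par, fixK) {
    kappa <- exp(par[1L])
    omegas <- exp(par[2:4])
    z <- par[5:6]
    w1 <- stats::plogis(z[1L])
    w2 <- (1 - w1) * stats::plogis(z[2L])
    weights <- c(w1, w2, 1 - w1 - w2)
    K <- if (fixK) 1 else exp(par[7L])
    list(kappa = kappa, omegas = omegas, weights = weights, K = K)
  }
  negll <- function(par, fixK) {
    p <- unpack(par, fixK)
    ll <- mixture_ll(p$kappa, p$omegas, p$weights, p$K)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- c(log(0.01), rep(log(1e-4), 3L), -6, -6)
  hi <- c(log(100), rep(log(99), 3L), 6, 6)
  fit_one <- function(fixK, starts) {
    lo2 <- c(lo, if (!fixK) log(1e-3))
    hi2 <- c(hi, if (!fixK) log(50))
    best <- NULL
    for (par0 in starts) {
      par0 <- pmin(pmax(par0, lo2), hi2)
      f <- try(stats::optim(par0, negll, fixK = fixK, method = "L-BFGS-B",
                            lower = lo2, upper = hi2,
                            control = list(maxit = opts$maxit %||% 400L,
                                           factr = opts$factr %||% 5e7)),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      if (is.null(best) || f$value < best$value) best <- f
    }
    best
  }
  rng <- make_rng(substream_seed(opts$seed %||% 1L, 42L))
  base_start <- c(log(2), log(c(0.05, 0.3, 1.1)), 0.4, 0.5)
  starts0 <- list(base_start)
  for (r in seq_len((opts$n_restarts %||% 2L) - 1L)) {
    starts0[[r + 1L]] <- base_start + (rng(length(base_start)) - 0.5) * 1.5
  }
  f0 <- fit_one(TRUE, starts0)
  if (is.null(f0)) stop("relax optimisation failed")
  # warm-start the alternative from the null optimum (K = 1 is interior)
  starts1 <- list(c(f0$par, 0))
  if ((opts$n_restarts %||% 2L) > 1L) {
    starts1[[2L]] <- c(f0$par, log(0.2))
  }
  f1 <- fit_one(FALSE, starts1)
  if (is.null(f1)) stop("relax optimisation failed")
  if (f1$value > f0$value) f1 <- list(par = c(f0$par, 0), value = f0$value)
  pars <- unpack(f1$par, FALSE)
  ord <- order(pars$omegas)
  statistic <- max(0, 2 * ((-f1$value) - (-f0$value)))
  p <- chi2_sf(statistic, 1L)
  direction <- if (p < alpha && pars$K < 1) "relaxed"
               else if (p < alpha && pars$K > 1) "intensified" else "none"
  structure(list(omegas = pars$omegas[ord], weights = pars$weights[ord],
                 kappa = pars$kappa, K = pars$K,
                 lnL_null = -f0$value, lnL_alt = -f1$value,
                 statistic = statistic, p = p, direction = direction,
                 alpha = alpha),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("relax_fit: K = %.3f, p = %.4g (%s)\n", x$K, x$p, x$direction))
  cat("  background omegas:", paste(sprintf("%.3f", x$omegas), collapse = ", "),
      "\n  weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}
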