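# Maximum-likelihood fitting of branch models, the nested LRT ladder, and
# its model-selection logic.

#' Fit a branch model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over kappa, one omega per class and
#' (optionally) all branch lengths, using bounded quasi-Newton optimisation
#' in log space with multiple restarts. Codon frequencies are fixed from the
#' data (`F3x4` by default) rather than estimated. omega is bounded to
#' `[1e-4, 99]` and kappa to `[0.01, 100]`.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [species_tree()] or `phylo` with branch lengths (used as
#'   starting values, or as fixed lengths when
#'   `opts$fix_branch_lengths = TRUE`).
#' @param spec A [branch_model_spec()].
#' @param opts List of options: `freq_method` ("F3x4"), `pi` (override
#'   frequencies), `fix_branch_lengths` (FALSE), `blen` (fixed lengths),
#'   `n_restarts` (3), `seed` (1), `init` (list with `kappa`, `omegas`),
#'   `maxit` (300), `factr` (1e7).
#' @return A `fit_result`: `spec`, `lnL`, `params` (kappa, omegas, pi,
#'   blen), `n_free_params`, `converged`, `n_restarts_used`.
#' @export
fit_branch_model <- function(aln, tree, spec, opts = list()) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  prep <- prep_pruning(aln, phy)
  pi <- opts$pi %||% codon_freqs(aln, opts$freq_method %||% "F3x4")
  fix_bl <- isTRUE(opts$fix_branch_lengths)
  blen0 <- opts$blen %||% phy$edge.length %||% rep(0.1, nrow(phy$edge))
  blen0 <- pmax(blen0, 1e-6)
  nc <- spec$n_classes
  ne <- nrow(phy$edge)
  n_restarts <- opts$n_restarts %||% 3L
  maxit <- opts$maxit %||% 300L
  factr <- opts$factr %||% 1e7
  init_kappa <- opts$init$kappa %||% 2
  init_omegas <- opts$init$omegas %||% rep(0.4, nc)
  if (length(init_omegas) == 1L) init_omegas <- rep(init_omegas, nc)

  lo <- c(log(0.01), rep(log(1e-4), nc), if (!fix_bl) rep(log(1e-7), ne))
  hi <- c(log(100), rep(log(99), nc), if (!fix_bl) rep(log(20), ne))
  negll <- function(par) {
    kappa <- exp(par[1L])
    omegas <- exp(par[2L:(1L + nc)])
    bl <- if (fix_bl) blen0 else exp(par[(2L + nc):(1L + nc + ne)])
    ll <- sum(prep$counts *
                loglik_from_prep(prep, spec, kappa, omegas, pi, bl))
    if (!is.finite(ll)) 1e10 else -ll
  }

  rng <- make_rng(substream_seed(opts$seed %||% 1L, 77L))
  best <- NULL
  used <- 0L
  for (r in seq_len(n_restarts)) {
    used <- r
    jit <- if (r == 1L) rep(0, 1L + nc + if (fix_bl) 0L else ne) else
      (rng(1L + nc + if (fix_bl) 0L else ne) - 0.5) * 2
    par0 <- c(log(init_kappa), log(init_omegas), if (!fix_bl) log(blen0)) + jit
    par0 <- pmin(pmax(par0, lo), hi)
    fit <- try(stats::optim(par0, negll, method = "L-BFGS-B", lower = lo,
                            upper = hi,
                            control = list(maxit = maxit, factr = factr)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (r >= (opts$min_restarts %||% 1L) && !is.null(best) &&
        best$convergence == 0 && isTRUE(opts$stop_on_converged)) break
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, lnL = -Inf,
                          params = list(kappa = NA, omegas = rep(NA, nc),
                                        pi = pi, blen = blen0),
                          n_free_params = 1L + nc + if (fix_bl) 0L else ne,
                          converged = FALSE, n_restarts_used = used),
                     class = "fit_result"))
  }
  par <- best$par
  kappa <- exp(par[1L])
  omegas <- exp(par[2L:(1L + nc)])
  bl <- if (fix_bl) blen0 else exp(par[(2L + nc):(1L + nc + ne)])
  structure(list(spec = spec, lnL = -best$value,
                 params = list(kappa = kappa, omegas = omegas, pi = pi,
                               blen = bl),
                 n_free_params = 1L + nc + if (fix_bl) 0L else ne,
                 converged = best$convergence == 0,
                 n_restarts_used = used),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result %s: lnL = %.4f, kappa = %.3f, omegas = %s%s\n",
              x$spec$model_id, x$lnL, x$params$kappa,
              paste(sprintf("%.4f", x$params$omegas), collapse = ", "),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic.
#' @param df Degrees of freedom (integer, at least 1).
#' @return Upper-tail probability.
#' @export
chi2_sf <- function(x, df) {
  if (any(df < 1)) stop("df must be >= 1")
  stopifnot(all(x >= 0))
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested branch-model fits
#'
#' Statistic `2 (lnL_alt - lnL_null)` clipped at zero, compared to
#' chi-square with `df` equal to the difference in free parameters.
#'
#' @param fit_null,fit_alt `fit_result`s of nested models on the same data.
#' @param alpha Significance threshold recorded on the result.
#' @return An `lrt_result`: `null_id`, `alt_id`, `statistic`, `df`, `p`,
#'   `significant`.
#' @export
lrt <- function(fit_null, fit_alt, alpha = 0.05) {
  if (!spec_is_nested(fit_null$spec, fit_alt$spec)) {
    stop("models ", fit_null$spec$model_id, " and ", fit_alt$spec$model_id,
         " are not nested")
  }
  df <- fit_alt$n_free_params - fit_null$n_free_params
  if (df < 1L) stop("alternative must have more free parameters than the null")
  statistic <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  p <- chi2_sf(statistic, df)
  structure(list(null_id = fit_null$spec$model_id,
                 alt_id = fit_alt$spec$model_id,
                 statistic = statistic, df = as.integer(df), p = p,
                 significant = p < alpha, alpha = alpha),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: statistic = %.3f, df = %d, p = %.4g%s\n",
              x$null_id, x$alt_id, x$statistic, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Fit a model ladder and select the best-supported branch model
#'
#' Fits every model in the ladder, computes likelihood-ratio tests for all
#' nested pairs, and selects the most complex model that significantly
#' rejects every simpler model nested in it while not being significantly
#' rejected by any more complex ladder model. Among equally complex
#' candidates the better log-likelihood wins.
#'
#' @param aln A [codon_alignment()].
#' @param tree A labelled [species_tree()].
#' @param ladder Ladder definition: list with `models` (named list: model id
#'   -> list of foreground label groups) and optionally `comparisons`
#'   (data.frame with columns `null`, `alt`). Defaults to the packaged
#'   14-model ladder ([default_model_ladder()]).
#' @param alpha Significance threshold.
#' @param opts Options passed to [fit_branch_model()].
#' @return List: `best_id`, `fits` (named), `lrts` (data.frame of all nested
#'   comparisons), `alpha`.
#' @export
run_ladder <- function(aln, tree, ladder = default_model_ladder(),
                       alpha = 0.05, opts = list()) {
  specs <- lapply(names(ladder$models), function(id) {
    branch_model_spec(tree, id, ladder$models[[id]])
  })
  names(specs) <- names(ladder$models)
  if (!is.null(ladder$comparisons)) {
    for (k in seq_len(nrow(ladder$comparisons))) {
      n_id <- ladder$comparisons$null[k]; a_id <- ladder$comparisons$alt[k]
      if (!spec_is_nested(specs[[n_id]], specs[[a_id]]) ||
          specs[[n_id]]$n_classes >= specs[[a_id]]$n_classes) {
        stop("ladder comparison ", n_id, " vs ", a_id, " is not properly nested")
      }
    }
  }
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (id in names(specs)) {
    o <- opts
    if (is.null(o$init) && id != names(specs)[1L] &&
        !is.null(fits[[names(specs)[1L]]])) {
      base <- fits[[names(specs)[1L]]]
      o$init <- list(kappa = base$params$kappa,
                     omegas = rep(base$params$omegas[1L], specs[[id]]$n_classes))
      if (!isTRUE(o$fix_branch_lengths)) o$blen_init <- base$params$blen
    }
    fits[[id]] <- fit_branch_model(aln, tree, specs[[id]], o)
  }
  lrts <- list()
  ids <- names(specs)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    si <- specs[[ids[i]]]; sj <- specs[[ids[j]]]
    if (si$n_classes < sj$n_classes && spec_is_nested(si, sj)) {
      r <- lrt(fits[[ids[i]]], fits[[ids[j]]], alpha)
      lrts[[length(lrts) + 1L]] <- data.frame(
        null = r$null_id, alt = r$alt_id, statistic = r$statistic,
        df = r$df, p = r$p, significant = r$significant,
        stringsAsFactors = FALSE)
    }
  }
  lrts <- if (length(lrts)) do.call(rbind, lrts) else
    data.frame(null = character(0), alt = character(0), statistic = numeric(0),
               df = integer(0), p = numeric(0), significant = logical(0))
  n_par <- vapply(fits, `[[`, numeric(1), "n_free_params")
  qualifies <- vapply(ids, function(id) {
    below <- lrts[lrts$alt == id, , drop = FALSE]
    above <- lrts[lrts$null == id, , drop = FALSE]
    all(below$significant) && !any(above$significant)
  }, logical(1))
  cand <- ids[qualifies]
  if (!length(cand)) cand <- ids[which.min(n_par)]  # fall back to simplest
  best <- cand[order(-n_par[cand],
                     -vapply(fits[cand], `[[`, numeric(1), "lnL"))][1L]
  list(best_id = best, fits = fits, lrts = lrts, alpha = alpha)
}

#' The packaged 14-model ladder (models A..N)
#'
#' Loads the machine-readable default ladder shipped with the package: one
#' background ratio plus foreground groups over the labelled clades
#' (A1 Pinnipedia, A2 Canidae, A3 Feliformia, B1 Cetacea, B2 Ruminantia,
#' C1 Chiroptera, D1 Rodentia) and stem branches (BranchA1, BranchB1),
#' together with the published LRT statistics and degrees of freedom for
#' each nested comparison.
#'
#' @return List with `models`, `comparisons` (data.frame: null, alt, df,
#'   lrt, p_printed).
#' @export
default_model_ladder <- function() {
  path <- system.file("extdata", "model_ladder.yaml", package = "geneloss")
  y <- yaml::read_yaml(path)
  models <- lapply(y$models, function(m) {
    if (is.null(m)) list() else lapply(m, unlist)
  })
  comp <- do.call(rbind, lapply(y$comparisons, function(cc) {
    data.frame(null = cc$null, alt = cc$alt, df = as.integer(cc$df),
               lrt = as.numeric(cc$lrt),
               p_printed = as.character(cc$p %||% NA_character_),
               stringsAsFactors = FALSE)
  }))
  list(models = models, comparisons = comp)
}
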