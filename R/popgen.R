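# Population-level loss-of-function statistics: allele and homozygote
# frequencies, Hardy-Weinberg tests, damaging-variant filtering, LoF density,
# observed/expected constraint with a Poisson LOEUF-style bound, windowed
# diversity with Tajima's D, and a JZS Bayes-factor one-sample test.

#' Allele and homozygous-minor-allele frequencies from genotype counts
#'
#' @param counts Length-3 vector `(n_AA, n_Aa, n_aa)` of genotype counts
#'   (major homozygote, heterozygote, minor homozygote).
#' @param population Label recorded on the result.
#' @param hwe_method Method passed to [hwe_test()].
#' @return A one-row `data.frame`: `population`, `n`, `allele_freq`,
#'   `hma_freq`, `hwe_p`.
#' @export
allele_and_hma_freqs <- function(counts, population = "pop",
                                 hwe_method = "chi2") {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty sample")
  data.frame(population = population, n = n,
             allele_freq = (counts[2L] + 2 * counts[3L]) / (2 * n),
             hma_freq = counts[3L] / n,
             hwe_p = hwe_test(counts, method = hwe_method),
             stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' `chi2` is the df-1 goodness-of-fit test against expected proportions
#' `p^2, 2pq, q^2` (optionally with Yates continuity correction,
#' `chi2_cc`); `exact` is the conditional exact test summing the
#' probabilities of all heterozygote counts no more probable than the one
#' observed.
#'
#' @param counts `(n_AA, n_Aa, n_aa)` genotype counts.
#' @param method `"chi2"`, `"chi2_cc"` or `"exact"`.
#' @return P-value.
#' @export
hwe_test <- function(counts, method = c("chi2", "chi2_cc", "exact")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty sample")
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  p <- 1 - q
  if (method %in% c("chi2", "chi2_cc")) {
    expd <- n * c(p^2, 2 * p * q, q^2)
    if (any(expd == 0)) return(1)  # monomorphic: nothing to test
    dev <- abs(counts - expd)
    if (method == "chi2_cc") dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / expd)
    return(chi2_sf(stat, 1L))
  }
  # exact: condition on allele counts, enumerate heterozygote numbers
  n_minor <- counts[2L] + 2 * counts[3L]
  hets <- seq(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  logpr <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) - lgamma(hom_min + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logpr - max(logpr))
  pr <- pr / sum(pr)
  obs <- pr[match(counts[2L], hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Filter variants most likely to be damaging
#'
#' ORF-disrupting consequences (`stop_gained`, `frameshift`) are kept
#' regardless of scores; missense variants are kept when PolyPhen lies in
#' `[0.7, 1]` and SIFT in `[0, 0.3]` (bounds inclusive). Missense records
#' missing either score are dropped; other consequences are dropped.
#'
#' @param records Variant `data.frame` with columns `consequence`,
#'   `polyphen`, `sift`.
#' @return Filtered `data.frame` (row order preserved).
#' @export
filter_damaging <- function(records) {
  lof <- records$consequence %in% c("stop_gained", "frameshift")
  mis <- records$consequence == "missense" &
    !is.na(records$polyphen) & !is.na(records$sift) &
    records$polyphen >= 0.7 & records$polyphen <= 1 &
    records$sift >= 0 & records$sift <= 0.3
  records[lof | mis, , drop = FALSE]
}

#' Density of damaging variants per kilobase of coding sequence
#'
#' @param n_variants Number of damaging variants.
#' @param cds_len_bp Coding length in base pairs.
#' @return Variants per kb.
#' @export
lof_density <- function(n_variants, cds_len_bp) {
  if (cds_len_bp <= 0) stop("cds_len_bp must be positive")
  stopifnot(n_variants >= 0)
  1000 * n_variants / cds_len_bp
}

#' Observed/expected LoF ratio and LOEUF-style upper bound
#'
#' Models the observed LoF count as Poisson with mean `lambda * expected`
#' and reports `oe = observed / expected` together with the upper end of the
#' two-sided `ci` confidence interval for `lambda` (the LOEUF-style bound):
#' the `lambda` whose lower-tail probability of at most `observed` events
#' equals `(1 - ci) / 2`.
#'
#' @param observed Observed LoF count.
#' @param expected Expected LoF count (> 0).
#' @param ci Confidence level of the two-sided interval (default 0.90).
#' @return `data.frame` with `observed`, `expected`, `oe`, `loeuf`.
#' @export
oe_and_loeuf <- function(observed, expected, ci = 0.90) {
  if (observed < 0) stop("observed must be non-negative")
  if (expected <= 0) stop("expected must be positive")
  alpha <- (1 - ci) / 2
  # P(X <= obs | mean) = alpha  <=>  mean = qgamma(1 - alpha, obs + 1)
  upper_mean <- stats::qgamma(1 - alpha, shape = observed + 1)
  data.frame(observed = observed, expected = expected,
             oe = observed / expected, loeuf = upper_mean / expected)
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  stopifnot(n >= 2L)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Windowed nucleotide diversity and Tajima's D
#'
#' Splits the region into non-overlapping windows of `window_bp` and, per
#' window, reports the number of segregating sites S, nucleotide diversity
#' per site (mean pairwise difference divided by window width), and
#' Tajima's D `(pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants. D is reported missing when `S = 0`.
#'
#' @param haplotypes n x S 0/1 matrix (rows are haplotypes).
#' @param positions 1-based bp positions of the S sites.
#' @param region_bp Total region length.
#' @param window_bp Window width (default 100 kb).
#' @return `data.frame`: `window_start`, `window_end` (1-based inclusive),
#'   `n_sequences`, `S`, `pi`, `tajima_d`.
#' @export
diversity_scan <- function(haplotypes, positions, region_bp,
                           window_bp = 100000L) {
  n <- nrow(haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  stopifnot(ncol(haplotypes) == length(positions))
  k <- tajima_constants(n)
  starts <- seq(1L, region_bp, by = window_bp)
  rows <- lapply(starts, function(s0) {
    e0 <- min(s0 + window_bp - 1L, region_bp)
    sel <- positions >= s0 & positions <= e0
    S <- sum(sel)
    if (S > 0L) {
      m <- haplotypes[, sel, drop = FALSE]
      derived <- colSums(m)
      pair_diffs <- sum(derived * (n - derived)) / choose(n, 2)  # total pi
      pi_site <- pair_diffs / (e0 - s0 + 1L)
      D <- if (S >= 1L) {
        denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
        if (denom > 0) (pair_diffs - S / k$a1) / denom else NA_real_
      } else NA_real_
    } else {
      pi_site <- 0; D <- NA_real_
    }
    data.frame(window_start = s0, window_end = e0, n_sequences = n, S = S,
               pi = pi_site, tajima_d = D)
  })
  do.call(rbind, rows)
}

#' JZS Bayes factor for a one-sample test
#'
#' Jeffreys-Zellner-Siow Bayes factor comparing H1 (Cauchy prior with scale
#' `prior_scale` on the standardised effect) against H0 (mean equal to
#' `h0`), computed by numerical integration of the noncentral-t likelihood
#' over the prior.
#'
#' @param values Numeric observations (n >= 2, nonzero variance).
#' @param h0 Null value of the mean.
#' @param prior_scale Cauchy prior scale (default 0.707).
#' @return List: `n`, `t`, `bf10`, `bf01`, `h0_value`.
#' @export
jzs_one_sample_bf <- function(values, h0, prior_scale = 0.707) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  t <- (mean(values) - h0) / (s / sqrt(n))
  bf <- jzs_bf_from_t(t, n, prior_scale)
  list(n = n, t = t, bf10 = bf, bf01 = 1 / bf, h0_value = h0)
}

#' JZS Bayes factor from a t statistic
#' @param t One-sample t statistic.
#' @param n Sample size.
#' @param prior_scale Cauchy prior scale.
#' @return `bf10`.
#' @export
jzs_bf_from_t <- function(t, n, prior_scale = 0.707) {
  nu <- n - 1
  # dt(ncp) attains ~1e-12 absolute accuracy and warns about it; that is far
  # below the tolerance that matters for a Bayes factor
  marg1 <- stats::integrate(function(delta) {
    suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, location = 0, scale = prior_scale)
  }, -Inf, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  marg0 <- stats::dt(t, df = nu)
  marg1 / marg0
}
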