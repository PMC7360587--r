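# Independent oracles used by the test suite. Each reimplements the checked
# quantity by a different route (exhaustive DP, brute-force enumeration,
# direct summation, grid quadrature) and stays independent of the package
# code paths it validates.

# optimal local-alignment score with affine gaps (Smith-Waterman DP);
# a gap of length L costs open + L * ext, matching the package's aligner
sw_local_score <- function(ref, tgt, match = 2, mismatch = -3,
                           open = 8, ext = 2) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(tgt, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in tgt (consume ref)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in ref (consume tgt)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# minimum number of single-origin events consistent with the evidence:
# cluster-mates must share an event and every event must be connected by
# shared mutations; computed by exhaustive minimisation over set partitions
loss_partition_oracle <- function(inact, clusters) {
  n <- length(inact)
  # grow partitions tip by tip (restricted growth strings)
  best <- n
  grow <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      blocks <- split(inact, assign)
      for (cl in clusters) {
        mem <- intersect(cl, inact)
        if (length(mem) > 1L &&
            length(unique(assign[match(mem, inact)])) != 1L) return(invisible())
      }
      # every block must be connected through shared clusters
      for (b in blocks) {
        if (length(b) == 1L) next
        reach <- b[1L]
        repeat {
          grew <- FALSE
          for (cl in clusters) {
            mem <- intersect(cl, b)
            if (length(mem) > 1L && any(mem %in% reach) &&
                !all(mem %in% reach)) { reach <- union(reach, mem); grew <- TRUE }
          }
          if (!grew) break
        }
        if (!setequal(reach, b)) return(invisible())
      }
      best <<- min(best, length(blocks))
      return(invisible())
    }
    for (a in seq_len(min(k + 1L, n))) grow(c(assign, a), max(k, a))
  }
  grow(integer(0), 0L)
  best
}

# brute-force minimum edge set covering the inactivated tips: every
# inactivated tip descends from exactly one chosen edge, no chosen edge
# covers a coding tip, and cluster-mates share their edge
loss_count_oracle <- function(phy, inact, clusters, coding = character(0)) {
  ntip <- length(phy$tip.label)
  ne <- nrow(phy$edge)
  below <- lapply(seq_len(ne), function(k) {
    node <- phy$edge[k, 2]
    tips <- if (node <= ntip) node else {
      keep <- node
      repeat {
        more <- phy$edge[phy$edge[, 1] %in% keep, 2]
        new <- setdiff(more, keep)
        if (!length(new)) break
        keep <- c(keep, new)
      }
      keep[keep <= ntip]
    }
    phy$tip.label[tips]
  })
  inact_idx <- match(inact, phy$tip.label)
  stopifnot(!anyNA(inact_idx))
  best <- length(inact)
  for (mask in seq_len(2^ne) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0)
    if (length(sel) >= best || length(sel) == 0L) next
    if (any(vapply(sel, function(k) any(coding %in% below[[k]]), logical(1)))) next
    cover <- vapply(inact, function(tp) {
      sum(vapply(sel, function(k) tp %in% below[[k]], logical(1)))
    }, integer(1))
    if (any(cover != 1L)) next
    owner <- vapply(inact, function(tp) {
      sel[vapply(sel, function(k) tp %in% below[[k]], logical(1))][1]
    }, numeric(1))
    ok <- TRUE
    for (cl in clusters) {
      mem <- intersect(cl, inact)
      if (length(mem) > 1L && length(unique(owner[mem])) != 1L) { ok <- FALSE; break }
    }
    if (ok) best <- length(sel)
  }
  best
}

# brute-force codon-site likelihood on a rooted 3-tip tree
# ((a:ta,b:tb):tn,c:tc) by direct summation over both internal states,
# with transition matrices from an independent matrix exponential
loglik3_oracle <- function(aln, ta, tb, tn, tc, kappa, omega, pi) {
  Q <- geneloss::codon_rate_matrix(kappa, omega, pi)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  Pa <- P(ta); Pb <- P(tb); Pn <- P(tn); Pc <- P(tc)
  mat <- aln$codon
  total <- 0
  for (k in seq_len(ncol(mat))) {
    a <- mat["a", k]; b <- mat["b", k]; cc <- mat["c", k]
    s <- 0
    for (r in 1:61) for (nn in 1:61) {
      s <- s + pi[r] * Pn[r, nn] * Pa[nn, a] * Pb[nn, b] * Pc[r, cc]
    }
    total <- total + log(s)
  }
  total
}

# expected disruption events for a planted locus: the planted indel/splice
# events plus every stop that a direct re-translation of the edited CDS
# predicts (frame tracked by construction)
translate_stops_oracle <- function(model, plan) {
  cds <- model$cds_seq
  widths <- model$exons[, 2] - model$exons[, 1]
  offs <- cumsum(c(0, head(widths, -1)))
  # apply CDS-level edits right-to-left (splice edits do not touch the CDS)
  cds_edits <- Filter(function(e) e$kind %in% c("stop", "deletion", "insertion",
                                                "substitution", "mask"), plan)
  at_of <- function(e) if (e$kind == "stop") 3 * e$codon - 2 else e$at
  cds_edits <- cds_edits[order(vapply(cds_edits, at_of, numeric(1)),
                               decreasing = TRUE)]
  for (e in cds_edits) {
    at <- at_of(e)
    if (e$kind == "stop") {
      substr(cds, at, at + 2) <- e$allele %||% "TAA"
    } else if (e$kind == "substitution") {
      substr(cds, at, at + nchar(e$to) - 1) <- e$to
    } else if (e$kind == "mask") {
      substr(cds, at, at + (e$len %||% 1) - 1) <- strrep("N", e$len %||% 1)
    } else if (e$kind == "deletion") {
      cds <- paste0(substr(cds, 1, at - 1), substr(cds, at + e$len, nchar(cds)))
    } else if (e$kind == "insertion") {
      if (is.null(e$seq)) stop("oracle plans use explicit `seq` insertions only")
      cds <- paste0(substr(cds, 1, at - 1), e$seq, substr(cds, at, nchar(cds)))
    }
  }
  n_cod <- nchar(cds) %/% 3
  stops <- character(0)
  for (j in seq_len(n_cod)) {
    cod <- substr(cds, 3 * j - 2, 3 * j)
    if (grepl("N", cod)) next
    if (cod %in% c("TAA", "TAG", "TGA")) stops <- c(stops, cod)
  }
  stops
}

# fine-grid midpoint quadrature for the JZS Bayes factor
jzs_grid_oracle <- function(t, n, r = 0.707, half_width = 60, step = 5e-4) {
  nu <- n - 1
  delta <- seq(-half_width, half_width, by = step)
  dens <- suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(n))) *
    stats::dcauchy(delta, 0, r)
  sum(dens) * step / stats::dt(t, df = nu)
}

# Tajima's D computed directly from its definition, coded independently
tajima_d_oracle <- function(hap) {
  n <- nrow(hap); S <- ncol(hap)
  if (S == 0) return(NA_real_)
  pw <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) pw <- pw + sum(hap[i, ] != hap[j, ])
  pi_tot <- pw / (n * (n - 1) / 2)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
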