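# Codon substitution machinery: 61-state reversible rate matrices with
# transition/transversion and dN/dS parameters, spectral transition
# probabilities, and a pruning likelihood over site patterns.

#' Build a codon alignment container
#'
#' Stores taxa and a taxa x codon-site integer matrix over the 61 sense
#' codons; gap codons (`---`) and codons containing non-ACGT characters are
#' missing (`NA`). Sense alignments must be free of stop codons.
#'
#' @param seqs Named character vector of equal-length, in-frame sequences.
#' @return A `codon_alignment` object with fields `taxa`, `codon` (integer
#'   matrix, values 1..61 or `NA`), `n_codons`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("alignment rows differ in length")
  if (len %% 3L != 0L) stop("alignment length not a multiple of 3")
  n_cod <- len %/% 3L
  mat <- matrix(NA_integer_, length(seqs), n_cod,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cods <- substring(toupper(seqs[[i]]), seq(1L, len, 3L), seq(3L, len, 3L))
    stops <- which(cods %in% STOP_CODONS)
    if (length(stops)) {
      stop("stop codon ", cods[stops[1L]], " in taxon ", names(seqs)[i],
           " at codon column ", stops[1L])
    }
    mat[i, ] <- match(cods, SENSE_CODONS)
  }
  structure(list(taxa = names(seqs), codon = mat, n_codons = n_cod),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$n_codons, "codons\n")
  invisible(x)
}

#' Curate a raw codon alignment for selection analysis
#'
#' Removes the terminal stop-codon column (when any row carries a stop
#' there), masks listed disrupted codons (premature stops, frameshifted
#' codons) to gaps in the affected taxon, and removes columns whose gap
#' fraction is `max_gap_frac` or more. A stop codon remaining after curation
#' is an error naming the taxon and column.
#'
#' @param raw Named character vector of gapped, in-frame aligned sequences.
#' @param disrupted_codons Named list: taxon -> integer codon columns (in the
#'   raw alignment's coordinates) to mask.
#' @param max_gap_frac Columns with at least this gap fraction are dropped.
#' @return A [codon_alignment()].
#' @export
curate_alignment <- function(raw, disrupted_codons = list(), max_gap_frac = 0.9) {
  stopifnot(length(raw) >= 2L, !is.null(names(raw)))
  len <- unique(nchar(raw))
  if (length(len) != 1L) stop("alignment rows differ in length")
  if (len %% 3L != 0L) stop("alignment length not a multiple of 3")
  n_cod <- len %/% 3L
  cods <- t(vapply(raw, function(s) {
    substring(toupper(s), seq(1L, len, 3L), seq(3L, len, 3L))
  }, character(n_cod)))
  if (n_cod > 0L && any(cods[, n_cod] %in% STOP_CODONS)) {
    cods <- cods[, -n_cod, drop = FALSE]
  }
  for (taxon in names(disrupted_codons)) {
    if (!taxon %in% rownames(cods)) stop("unknown taxon in disrupted_codons: ", taxon)
    pos <- disrupted_codons[[taxon]]
    if (any(pos < 1L | pos > ncol(cods))) stop("disrupted codon outside alignment for ", taxon)
    cods[taxon, pos] <- "---"
  }
  is_gap <- matrix(grepl("[^ACGT]", cods), nrow(cods))
  gap_frac <- colMeans(is_gap)
  keep <- gap_frac < max_gap_frac
  cods <- cods[, keep, drop = FALSE]
  bad <- which(matrix(cods %in% STOP_CODONS, nrow(cods)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("stop codon remains after curation in taxon ", rownames(cods)[bad[1L, 1L]],
         " at column ", bad[1L, 2L],
         "; list it in disrupted_codons to mask it")
  }
  seqs <- apply(cods, 1L, paste, collapse = "")
  codon_alignment(stats::setNames(seqs, rownames(cods)))
}

#' Equilibrium codon frequencies from an alignment
#'
#' `F3x4` uses position-specific nucleotide frequencies (the usual default of
#' codon-model software), `F1x4` a single nucleotide distribution, `F61`
#' empirical codon proportions. Frequencies are floored at 1e-8 and
#' renormalised so every sense codon stays reachable.
#'
#' @param aln A [codon_alignment()].
#' @param method One of `"F3x4"`, `"F1x4"`, `"F61"`.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
codon_freqs <- function(aln, method = c("F3x4", "F1x4", "F61")) {
  method <- match.arg(method)
  obs <- aln$codon[!is.na(aln$codon)]
  cods <- SENSE_CODONS[obs]
  if (method == "F61") {
    cnt <- table(factor(cods, levels = SENSE_CODONS)) + 0.5
    pi <- as.numeric(cnt) / sum(cnt)
  } else {
    mat <- do.call(rbind, strsplit(cods, ""))
    if (method == "F3x4") {
      f <- lapply(1:3, function(p) {
        tab <- table(factor(mat[, p], levels = NUC)) + 0.5
        as.numeric(tab) / sum(tab)
      })
    } else {
      tab <- table(factor(as.vector(mat), levels = NUC)) + 0.5
      f <- rep(list(as.numeric(tab) / sum(tab)), 3L)
    }
    cm <- do.call(rbind, strsplit(SENSE_CODONS, ""))
    pi <- f[[1L]][match(cm[, 1L], NUC)] * f[[2L]][match(cm[, 2L], NUC)] *
      f[[3L]][match(cm[, 3L], NUC)]
    pi <- pi / sum(pi)
  }
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  pi
}

#' Codon frequencies from specified nucleotide frequencies (F3x4 form)
#' @param f Either a length-4 nucleotide frequency vector (A,C,G,T) used at
#'   all three positions or a list of three such vectors.
#' @return Numeric vector of 61 sense-codon frequencies summing to 1.
#' @export
f3x4_freqs <- function(f) {
  if (!is.list(f)) f <- rep(list(f), 3L)
  stopifnot(length(f) == 3L, all(vapply(f, length, 1L) == 4L))
  f <- lapply(f, function(v) v / sum(v))
  cm <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  pi <- f[[1L]][match(cm[, 1L], NUC)] * f[[2L]][match(cm[, 2L], NUC)] *
    f[[3L]][match(cm[, 3L], NUC)]
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  pi
}

#' Codon substitution rate matrix
#'
#' Instantaneous rate i -> j is zero for multi-nucleotide changes and
#' otherwise `pi_j * kappa^[transition] * omega^[nonsynonymous]`, with the
#' matrix scaled so the mean substitution rate at stationarity is 1 (branch
#' lengths are expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS ratio.
#' @param pi 61 sense-codon frequencies.
#' @return 61 x 61 rate matrix (rows sum to zero).
#' @export
codon_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L)
  Q <- matrix(0, 61L, 61L, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  rate <- pi[CODON_PAIRS[, "j"]] *
    kappa^CODON_PAIRS[, "ts"] * omega^CODON_PAIRS[, "nonsyn"]
  Q[CODON_PAIRS[, c("i", "j")]] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# spectral decomposition of the reversible codon chain for fast P(t);
# returns C1 diag(exp(lambda t)) C2 pieces
codon_eigen <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       C1 = e$vectors / sq,
       C2 = t(e$vectors) * rep(sq, each = 61L))
}

# transition probability matrix over time t from a codon_eigen system
codon_pmat <- function(es, t) {
  P <- es$C1 %*% (exp(es$values * t) * es$C2)
  P[P < 0] <- 0
  P
}

# precompute pruning structures: site patterns, postorder edges, tip states
prep_pruning <- function(aln, phy) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  miss <- setdiff(phy$tip.label, aln$taxa)
  if (length(miss)) stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  mat <- aln$codon[phy$tip.label, , drop = FALSE]
  key <- apply(mat, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  counts <- as.numeric(table(key)[key[first]])
  tipstate <- mat[, first, drop = FALSE]
  po <- ape::reorder.phylo(phy, "postorder")
  ordkey <- paste(phy$edge[, 1L], phy$edge[, 2L])
  pokey <- paste(po$edge[, 1L], po$edge[, 2L])
  orig_row <- match(pokey, ordkey)
  list(ntip = ntip, npat = sum(first), counts = counts, tipstate = tipstate,
       edge = po$edge, orig_row = orig_row, root = ntip + 1L,
       n_nodes = ntip + phy$Nnode)
}

# per-pattern log-likelihood via Felsenstein pruning with column rescaling;
# Plist follows prep$edge (postorder) order
prune_site_loglik <- function(prep, Plist, pi) {
  npat <- prep$npat
  partial <- vector("list", prep$n_nodes)
  lsc <- vector("list", prep$n_nodes)
  for (k in seq_len(nrow(prep$edge))) {
    pa <- prep$edge[k, 1L]; ch <- prep$edge[k, 2L]
    if (ch <= prep$ntip) {
      st <- prep$tipstate[ch, ]
      contrib <- matrix(1, 61L, npat)
      ok <- which(!is.na(st))
      if (length(ok)) contrib[, ok] <- Plist[[k]][, st[ok], drop = FALSE]
      ls <- NULL
    } else {
      contrib <- Plist[[k]] %*% partial[[ch]]
      ls <- lsc[[ch]]
    }
    if (is.null(partial[[pa]])) {
      partial[[pa]] <- contrib
      lsc[[pa]] <- if (is.null(ls)) numeric(npat) else ls
    } else {
      m <- partial[[pa]] * contrib
      if (!is.null(ls)) lsc[[pa]] <- lsc[[pa]] + ls
      cs <- colSums(m)
      cs[cs == 0] <- .Machine$double.xmin
      partial[[pa]] <- m * rep(1 / cs, each = 61L)
      lsc[[pa]] <- lsc[[pa]] + log(cs)
    }
  }
  L <- colSums(pi * partial[[prep$root]])
  L[L <= 0] <- .Machine$double.xmin
  log(L) + lsc[[prep$root]]
}

#' Branch-model log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense codons; gap/ambiguous codons enter
#' as missing data (partial likelihood of ones). Each omega class uses its
#' own rate matrix, scaled to mean rate 1 at stationarity.
#'
#' @param aln A [codon_alignment()].
#' @param tree A [species_tree()] or `phylo` object (tips must be in the
#'   alignment).
#' @param spec A [branch_model_spec()] covering every edge.
#' @param params List with `kappa`, `omegas` (one per class), `pi` (61
#'   frequencies), and optionally `blen` (per-edge lengths in the order of
#'   `phylo$edge` rows; defaults to the tree's branch lengths).
#' @return Log-likelihood (scalar).
#' @export
codon_loglik <- function(aln, tree, spec, params) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  prep <- prep_pruning(aln, phy)
  blen <- params$blen %||% phy$edge.length
  if (is.null(blen)) stop("no branch lengths available")
  ll <- loglik_from_prep(prep, spec, params$kappa, params$omegas, params$pi, blen)
  sum(prep$counts * ll)
}

loglik_from_prep <- function(prep, spec, kappa, omegas, pi, blen) {
  es <- lapply(omegas, function(w) codon_eigen(kappa, w, pi))
  Plist <- vector("list", nrow(prep$edge))
  for (k in seq_len(nrow(prep$edge))) {
    r <- prep$orig_row[k]
    Plist[[k]] <- codon_pmat(es[[spec$edge_class[r]]], blen[r])
  }
  prune_site_loglik(prep, Plist, pi)
}

#' Define a branch model: edges mapped to omega classes
#'
#' @param tree A [species_tree()] with clade/branch labels, or a `phylo`
#'   object when `groups` is given as edge indices.
#' @param model_id Identifier (e.g. `"A"`..`"N"`).
#' @param groups List of foreground groups, each a character vector of
#'   clade/branch labels (or an integer vector of edge rows). Unlisted edges
#'   form class 1 (the background `omega_0`); group `i` becomes class
#'   `i + 1`. An empty list is the one-ratio model.
#' @return A `branch_model_spec`: `model_id`, `edge_class` (integer per edge
#'   row), `n_classes`.
#' @export
branch_model_spec <- function(tree, model_id, groups = list()) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  ne <- nrow(phy$edge)
  cls <- rep(1L, ne)
  if (length(groups)) {
    for (g in seq_along(groups)) {
      rows <- label_edge_rows(tree, groups[[g]])
      if (any(cls[rows] != 1L)) {
        stop("model ", model_id, ": edge assigned to two omega classes")
      }
      cls[rows] <- g + 1L
    }
  }
  structure(list(model_id = model_id, edge_class = cls,
                 n_classes = max(cls)), class = "branch_model_spec")
}

label_edge_rows <- function(tree, labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  if (!inherits(tree, "species_tree")) {
    stop("label-based groups need a species_tree with labels")
  }
  rows <- integer(0)
  for (lab in labels) {
    if (lab %in% names(tree$clade_edges)) {
      rows <- c(rows, tree$clade_edges[[lab]])
    } else if (lab %in% names(tree$branch_edges)) {
      rows <- c(rows, tree$branch_edges[[lab]])
    } else {
      stop("unknown clade/branch label: ", lab)
    }
  }
  unique(rows)
}

#' Is one branch model nested in another?
#'
#' `null_spec` is nested in `alt_spec` when the alternative's class partition
#' refines the null's (every alternative class lies inside one null class),
#' so the null arises by equating alternative classes.
#'
#' @param null_spec,alt_spec [branch_model_spec()] objects on the same tree.
#' @return Logical.
#' @export
spec_is_nested <- function(null_spec, alt_spec) {
  a <- null_spec$edge_class; b <- alt_spec$edge_class
  if (length(a) != length(b)) stop("specs are on different trees")
  all(tapply(a, b, function(v) length(unique(v)) == 1L))
}
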