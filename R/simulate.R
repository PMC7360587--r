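# Synthetic-data generators with known truth: codon alignments evolved under
# branch (and site-mixture) omega models, gene loci with planted ORF
# disruptions, read-evidence pileup summaries, genotype panels under HWE or
# inbreeding, and neutral coalescent haplotypes. Every generator is
# deterministic given its seed and returns its truth alongside the data.

#' Compact labelled species tree for simulation studies
#'
#' A 12-tip tree carrying the full label set used by the model ladder
#' (clades A1, A2, A3, B1, B2, C1, D1 and stem branches BranchA1, BranchB1),
#' with two unlabelled background tips. Branch lengths are in expected
#' substitutions per codon. Small enough that whole-ladder simulation
#' studies stay cheap, while every foreground group exists.
#'
#' @return A [species_tree()].
#' @export
make_demo_species_tree <- function() {
  txt <- paste0(
    "((((a1x:0.06,a1y:0.06):0.05,(a2:0.09,a3:0.09):0.03):0.04,",
    "((b1x:0.06,b1y:0.06):0.05,b2:0.11):0.04):0.03,",
    "((c1:0.11,d1:0.11):0.03,(out1:0.08,out2:0.08):0.05):0.03);")
  phy <- ape::read.tree(text = txt)
  species_tree(phy,
               clades = list(A1 = c("a1x", "a1y"), A2 = "a2", A3 = "a3",
                             B1 = c("b1x", "b1y"), B2 = "b2", C1 = "c1",
                             D1 = "d1"),
               branches = list(BranchA1 = c("a1x", "a1y"),
                               BranchB1 = c("b1x", "b1y")))
}

# simulate tip codon states given per-edge transition matrices
sim_codon_engine <- function(phy, Plist, pi, n) {
  cw <- ape::reorder.phylo(phy, "cladewise")
  key <- paste(phy$edge[, 1L], phy$edge[, 2L])
  ord <- match(paste(cw$edge[, 1L], cw$edge[, 2L]), key)
  ntip <- length(phy$tip.label)
  states <- matrix(NA_integer_, ntip + phy$Nnode, n)
  states[ntip + 1L, ] <- sample.int(61L, n, replace = TRUE, prob = pi)
  for (k in seq_len(nrow(cw$edge))) {
    pa <- cw$edge[k, 1L]; ch <- cw$edge[k, 2L]
    P <- Plist[[ord[k]]]
    ps <- states[pa, ]
    out <- integer(n)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[ch, ] <- out
  }
  states[seq_len(ntip), , drop = FALSE]
}

#' Simulate a codon alignment under a branch model
#'
#' Root codons are drawn from `pi`; each branch evolves its parent state by
#' the transition kernel `exp(t Q)` of the branch's omega class. Stop codons
#' can never arise (the chain lives on the 61 sense codons).
#'
#' @param tree A [species_tree()] or `phylo` with branch lengths.
#' @param spec A [branch_model_spec()].
#' @param params List with `kappa`, `omegas` (one per class), `pi`, and
#'   optionally `blen`.
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return List with `aln` (a [codon_alignment()]) and `truth` (scenario
#'   parameters).
#' @export
sim_codon_alignment <- function(tree, spec, params, n_codons, seed) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  blen <- params$blen %||% phy$edge.length
  es <- lapply(params$omegas, function(w) codon_eigen(params$kappa, w, params$pi))
  Plist <- lapply(seq_len(nrow(phy$edge)), function(k) {
    codon_pmat(es[[spec$edge_class[k]]], blen[k])
  })
  tips <- with_seed(substream_seed(seed, 1L), {
    sim_codon_engine(phy, Plist, params$pi, n_codons)
  })
  seqs <- apply(tips, 1L, function(row) paste(SENSE_CODONS[row], collapse = ""))
  names(seqs) <- phy$tip.label
  list(aln = codon_alignment(seqs),
       truth = list(scenario = "branch_model", model_id = spec$model_id,
                    kappa = params$kappa, omegas = params$omegas,
                    blen = blen, n_codons = n_codons, seed = seed))
}

#' Simulate a codon alignment under a site-mixture with selection intensity K
#'
#' Sites draw omega from background categories `(omegas, weights)`; on the
#' `test_edges` each category's omega is raised to the power `K`.
#'
#' @param tree A [species_tree()] or `phylo` with branch lengths.
#' @param test_edges Edge rows or labels receiving `omega^K`.
#' @param kappa,omegas,weights,pi,K Model parameters.
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return List with `aln` and `truth` (includes per-site categories).
#' @export
sim_relax_alignment <- function(tree, test_edges, kappa, omegas, weights, pi,
                                K, n_codons, seed) {
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  rows <- if (is.character(test_edges)) label_edge_rows(tree, test_edges)
          else as.integer(test_edges)
  ne <- nrow(phy$edge)
  cls <- ifelse(seq_len(ne) %in% rows, 2L, 1L)
  cats <- with_seed(substream_seed(seed, 2L), {
    sample.int(length(omegas), n_codons, replace = TRUE, prob = weights)
  })
  tips <- matrix(NA_integer_, length(phy$tip.label), n_codons)
  for (c3 in unique(cats)) {
    idx <- which(cats == c3)
    es_bg <- codon_eigen(kappa, omegas[c3], pi)
    es_fg <- codon_eigen(kappa, min(max(omegas[c3]^K, 1e-6), 5e3), pi)
    Plist <- lapply(seq_len(ne), function(k) {
      codon_pmat(if (cls[k] == 2L) es_fg else es_bg, phy$edge.length[k])
    })
    tips[, idx] <- with_seed(substream_seed(seed, 100L + c3), {
      sim_codon_engine(phy, Plist, pi, length(idx))
    })
  }
  seqs <- apply(tips, 1L, function(row) paste(SENSE_CODONS[row], collapse = ""))
  names(seqs) <- phy$tip.label
  list(aln = codon_alignment(seqs),
       truth = list(scenario = "relax", K = K, omegas = omegas,
                    weights = weights, kappa = kappa, site_category = cats,
                    seed = seed))
}

#' Simulate a genomic locus with planted ORF disruptions
#'
#' Builds a genomic slice by joining the model's reference exons with random
#' introns carrying the declared splice dialects, then applies planted edits.
#' Edit kinds: `stop` (replace codon `codon` by stop `allele`, default TAA),
#' `substitution` (`at`, `to`), `deletion` (`at`, `len`), `insertion` (`at`,
#' `len` or `seq`), `splice` (`intron`, `site` = donor/acceptor, `to`), and
#' `mask` (`at`, `len`: replace by N). CDS coordinates are 1-based.
#'
#' @param model A [gene_model()].
#' @param plan List of edits (possibly empty).
#' @param intron_len Length of each simulated intron (at least 10).
#' @param seed Integer seed.
#' @return List with `genomic` (slice in CDS orientation), `truth`
#'   (data.frame of planted disruptions with expected detection fields), and
#'   `cds_to_slice` (coordinate map).
#' @export
sim_gene_locus <- function(model, plan = list(), intron_len = 500L, seed = 1L) {
  stopifnot(intron_len >= 10L)
  widths <- model$exons[, 2L] - model$exons[, 1L]
  n_ex <- length(widths)
  offs <- cumsum(c(0L, utils::head(widths, -1L)))
  introns <- with_seed(substream_seed(seed, 3L), {
    lapply(seq_len(n_ex - 1L), function(i) {
      mid <- paste(sample(NUC, intron_len - 4L, replace = TRUE), collapse = "")
      paste0(model$donor_dialect[i], mid, "AG")
    })
  })
  pieces <- character(0)
  cds_to_slice <- integer(nchar(model$cds_seq))
  pos <- 0L
  for (i in seq_len(n_ex)) {
    exon <- substr(model$cds_seq, offs[i] + 1L, offs[i] + widths[i])
    cds_to_slice[(offs[i] + 1L):(offs[i] + widths[i])] <- pos + seq_len(widths[i])
    pieces <- c(pieces, exon)
    pos <- pos + widths[i]
    if (i < n_ex) {
      pieces <- c(pieces, introns[[i]])
      pos <- pos + intron_len
    }
  }
  slice <- paste(pieces, collapse = "")
  intron_start <- function(i) cds_to_slice[offs[i] + widths[i]] + 1L  # 1-based
  cds_len <- nchar(model$cds_seq)

  truth <- list()
  # apply edits right-to-left along the CDS so slice coordinates of pending
  # (more upstream) edits stay valid; splice edits sort between their exons
  sort_key <- vapply(plan, function(e) {
    switch(e$kind,
           stop = 3 * e$codon - 2,
           splice = if (e$site == "donor") offs[e$intron] + widths[e$intron] + 0.1
                    else offs[e$intron + 1L] + 0.9,
           as.numeric(e$at))
  }, numeric(1))
  ord <- order(sort_key, decreasing = TRUE)
  for (e in plan[ord]) {
    if (e$kind == "splice") {
      i <- e$intron
      stopifnot(i >= 1L, i <= n_ex - 1L)
      s0 <- intron_start(i)
      if (e$site == "donor") {
        substr(slice, s0, s0 + 1L) <- e$to
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "splice_loss", exon_index = i, cds_nt_pos = offs[i] + widths[i],
          indel_len = 0L, frameshift = FALSE, splice_site = "donor",
          observed_site = e$to, stringsAsFactors = FALSE)
      } else {
        substr(slice, s0 + intron_len - 2L, s0 + intron_len - 1L) <- e$to
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "splice_loss", exon_index = i + 1L, cds_nt_pos = offs[i + 1L] + 1L,
          indel_len = 0L, frameshift = FALSE, splice_site = "acceptor",
          observed_site = e$to, stringsAsFactors = FALSE)
      }
      next
    }
    at <- if (e$kind == "stop") 3L * e$codon - 2L else as.integer(e$at)
    len <- as.integer(e$len %||% (if (e$kind == "stop") 3L else 1L))
    if (at < 1L || at > cds_len || (e$kind != "insertion" && at + len - 1L > cds_len)) {
      stop("edit outside CDS (at = ", at, ", len = ", len, ")")
    }
    ex_i <- max(which(offs < at))
    s_at <- cds_to_slice[at]
    if (e$kind != "insertion" &&
        (at + len - 1L) > (offs[ex_i] + widths[ex_i])) {
      stop("edit crosses an exon boundary; place planted edits within one exon")
    }
    if (e$kind == "stop") {
      allele <- e$allele %||% "TAA"
      stopifnot(allele %in% STOP_CODONS)
      substr(slice, s_at, s_at + 2L) <- allele
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "premature_stop", exon_index = ex_i, cds_nt_pos = at,
        indel_len = 0L, frameshift = FALSE, splice_site = NA_character_,
        observed_site = NA_character_, stringsAsFactors = FALSE)
    } else if (e$kind == "substitution") {
      substr(slice, s_at, s_at + nchar(e$to) - 1L) <- e$to
    } else if (e$kind == "mask") {
      substr(slice, s_at, s_at + len - 1L) <- strrep("N", len)
    } else if (e$kind == "deletion") {
      slice <- paste0(substr(slice, 1L, s_at - 1L),
                      substr(slice, s_at + len, nchar(slice)))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "deletion", exon_index = ex_i, cds_nt_pos = at,
        indel_len = len, frameshift = (len %% 3L) != 0L,
        splice_site = NA_character_, observed_site = NA_character_,
        stringsAsFactors = FALSE)
    } else if (e$kind == "insertion") {
      ins <- e$seq %||% with_seed(substream_seed(seed, 17L + at), {
        paste(sample(NUC, len, replace = TRUE), collapse = "")
      })
      len <- nchar(ins)
      slice <- paste0(substr(slice, 1L, s_at - 1L), ins,
                      substr(slice, s_at, nchar(slice)))
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "insertion", exon_index = ex_i, cds_nt_pos = at,
        indel_len = len, frameshift = (len %% 3L) != 0L,
        splice_site = NA_character_, observed_site = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      stop("unknown edit kind: ", e$kind)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, rev(truth)) else
    data.frame(kind = character(0), exon_index = integer(0),
               cds_nt_pos = integer(0), indel_len = integer(0),
               frameshift = logical(0), splice_site = character(0),
               observed_site = character(0), stringsAsFactors = FALSE)
  list(genomic = slice, truth = truth_df, cds_to_slice = cds_to_slice,
       seed = seed)
}

#' Simulate read-evidence summaries for disruption events
#'
#' Each project contributes `depth` reads per event; the number of disrupted
#' reads is binomial with the disrupted-allele frequency.
#'
#' @param events Event `data.frame` (keys taken via [event_key()]).
#' @param depth Reads per project per event.
#' @param disrupted_allele_freq Frequency of the disrupted allele in `[0,1]`.
#' @param n_projects Number of independent projects.
#' @param seed Integer seed.
#' @return Evidence `data.frame` (`project_id`, `species`, `event_key`,
#'   `reads_disrupted`, `reads_intact`).
#' @export
sim_read_evidence <- function(events, depth, disrupted_allele_freq, n_projects,
                              seed = 1L) {
  if (disrupted_allele_freq < 0 || disrupted_allele_freq > 1) {
    stop("disrupted_allele_freq must lie in [0, 1]")
  }
  if (n_projects == 0L || nrow(events) == 0L) {
    return(data.frame(project_id = character(0), species = character(0),
                      event_key = character(0), reads_disrupted = integer(0),
                      reads_intact = integer(0), stringsAsFactors = FALSE))
  }
  keys <- event_key(events)
  with_seed(substream_seed(seed, 4L), {
    do.call(rbind, lapply(seq_len(n_projects), function(p) {
      dis <- stats::rbinom(length(keys), depth, disrupted_allele_freq)
      data.frame(project_id = sprintf("SRP%03d", p), species = events$species,
                 event_key = keys, reads_disrupted = dis,
                 reads_intact = depth - dis, stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate genotype panels under HWE or inbreeding
#'
#' Genotype probabilities are `(1-q)^2 + f q (1-q)`, `2 q (1-q) (1-f)` and
#' `q^2 + f q (1-q)` for the homozygous-major, heterozygous and
#' homozygous-minor classes.
#'
#' @param pop_freqs Named numeric vector: population -> minor-allele
#'   frequency `q`.
#' @param n_per_pop Individuals per population.
#' @param inbreeding_f Inbreeding coefficient `f` in `[0, 1]`.
#' @param seed Integer seed.
#' @return `data.frame` with `population`, `n_AA`, `n_Aa`, `n_aa`, `q_true`.
#' @export
sim_genotypes <- function(pop_freqs, n_per_pop, inbreeding_f = 0, seed = 1L) {
  if (any(pop_freqs < 0 | pop_freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  if (inbreeding_f < 0 || inbreeding_f > 1) stop("inbreeding_f must lie in [0, 1]")
  with_seed(substream_seed(seed, 5L), {
    rows <- lapply(names(pop_freqs), function(pop) {
      q <- pop_freqs[[pop]]
      pr <- c((1 - q)^2 + inbreeding_f * q * (1 - q),
              2 * q * (1 - q) * (1 - inbreeding_f),
              q^2 + inbreeding_f * q * (1 - q))
      n <- as.vector(stats::rmultinom(1L, n_per_pop, pr))
      data.frame(population = pop, n_AA = n[1L], n_Aa = n[2L], n_aa = n[3L],
                 q_true = q, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate haplotypes under the standard neutral coalescent
#'
#' Kingman coalescent with time in units of 2N generations (pairwise
#' coalescence rate 1) and infinite-sites mutations at rate `theta / 2` per
#' lineage placed uniformly over the region.
#'
#' @param n Number of haplotypes (at least 2).
#' @param theta Population mutation rate `4 N mu` per locus.
#' @param region_bp Region length in base pairs.
#' @param seed Integer seed.
#' @return List: `haplotypes` (n x S 0/1 matrix), `positions` (1-based bp),
#'   `tmrca`, `tree_length`, `region_bp`.
#' @export
sim_coalescent_haplotypes <- function(n, theta, region_bp = 100000L, seed = 1L) {
  if (n < 2L) stop("need at least 2 haplotypes")
  with_seed(substream_seed(seed, 6L), {
    active <- as.list(seq_len(n))   # descendant tip sets of active lineages
    birth <- rep(0, n)              # time each active lineage started
    t <- 0
    branch_sets <- list(); branch_len <- numeric(0)
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + stats::rexp(1L, k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      for (idx in pair) {
        branch_sets[[length(branch_sets) + 1L]] <- active[[idx]]
        branch_len <- c(branch_len, t - birth[idx])
      }
      merged <- c(active[[pair[1L]]], active[[pair[2L]]])
      active[pair] <- NULL
      birth <- birth[-pair]
      active[[length(active) + 1L]] <- merged
      birth <- c(birth, t)
    }
    n_mut <- stats::rpois(length(branch_len), theta / 2 * branch_len)
    S <- sum(n_mut)
    hap <- matrix(0L, n, S)
    col <- 0L
    for (b in seq_along(branch_len)) {
      if (n_mut[b] > 0L) {
        for (m in seq_len(n_mut[b])) {
          col <- col + 1L
          hap[branch_sets[[b]], col] <- 1L
        }
      }
    }
    positions <- if (S > 0L) sort(sample.int(region_bp, S, replace = TRUE)) else integer(0)
    list(haplotypes = hap, positions = positions, tmrca = t,
         tree_length = sum(branch_len), region_bp = region_bp, seed = seed)
  })
}
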