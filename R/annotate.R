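# Reference-guided exon mapping and ORF-disruption detection: an algorithmic,
# auditable stand-in for manual gene annotation of candidate pseudogenes.

#' Map reference exons onto a genomic slice
#'
#' Each reference exon is sought, in order, by local alignment (match +2,
#' mismatch -3, gap open -8, gap extend -2) within the part of the slice that
#' follows the previous exon. An exon is accepted when its alignment identity
#' is at least `min_identity` over at least `min_coverage` of its length;
#' otherwise it is returned with `missing_data = TRUE`. Splice boundaries are
#' refined within `refine_bp` bases to maximise conformity with the declared
#' splice dialect, but only when the shifted bases are compatible with the
#' reference (so a genuinely mutated splice site is not explained away).
#' Flanking dinucleotides are read from the two bases outside each mapped
#' exon.
#'
#' @param model A [gene_model()].
#' @param genomic Genomic slice (character scalar), already in CDS
#'   orientation.
#' @param min_identity Minimum alignment identity over non-gap columns.
#' @param min_coverage Minimum fraction of the exon length aligned.
#' @param refine_bp Maximum boundary shift when refining splice sites.
#' @return List of `exon_alignment` records (one per reference exon) with
#'   fields `exon_index`, `ref_aligned`, `tgt_aligned`, `tgt_interval`
#'   (0-based half-open), `ref_span` (1-based covered reference-exon range),
#'   `identity`, `acceptor_obs`, `donor_obs`, `missing_data`.
#' @export
map_exons <- function(model, genomic, min_identity = 0.6, min_coverage = 0.6,
                      refine_bp = 12L) {
  stopifnot(inherits(model, "gene_model"))
  genomic <- toupper(genomic)
  if (!nzchar(genomic)) stop("genomic slice is empty")
  n_ex <- nrow(model$exons)
  widths <- model$exons[, 2L] - model$exons[, 1L]
  offs <- cumsum(c(0L, utils::head(widths, -1L)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  cursor <- 0L
  out <- vector("list", n_ex)
  for (i in seq_len(n_ex)) {
    ref_ex <- substr(model$cds_seq, offs[i] + 1L, offs[i] + widths[i])
    rec <- list(exon_index = i, ref_aligned = NA_character_,
                tgt_aligned = NA_character_, tgt_interval = c(NA_integer_, NA_integer_),
                ref_span = c(NA_integer_, NA_integer_), identity = NA_real_,
                acceptor_obs = NA_character_, donor_obs = NA_character_,
                missing_data = TRUE)
    region_start <- cursor
    if (region_start < nchar(genomic)) {
      region <- substr(genomic, region_start + 1L, nchar(genomic))
      pa <- Biostrings::pairwiseAlignment(pattern = ref_ex, subject = region,
                                          type = "local",
                                          substitutionMatrix = submat,
                                          gapOpening = 8, gapExtension = 2)
      r_start <- Biostrings::start(Biostrings::pattern(pa))
      r_end <- Biostrings::end(Biostrings::pattern(pa))
      t_start0 <- region_start + Biostrings::start(Biostrings::subject(pa)) - 1L
      t_end0 <- region_start + Biostrings::end(Biostrings::subject(pa))
      # re-align the full exon pattern-globally inside a padded window so
      # that indels clipped off the local alignment's ends stay visible
      pad <- 30L + max(0L, widths[i] - (r_end - r_start + 1L))
      win_s0 <- max(region_start, t_start0 - (r_start - 1L) - pad)
      win_e0 <- min(nchar(genomic), t_end0 + (widths[i] - r_end) + pad)
      window <- substr(genomic, win_s0 + 1L, win_e0)
      pg <- Biostrings::pairwiseAlignment(pattern = ref_ex, subject = window,
                                          type = "global-local",
                                          substitutionMatrix = submat,
                                          gapOpening = 8, gapExtension = 2)
      pc <- strsplit(as.character(Biostrings::pattern(pg)), "")[[1L]]
      sc <- strsplit(as.character(Biostrings::subject(pg)), "")[[1L]]
      # trim terminal target-only columns (ref gap at either end)
      keep <- which(pc != "-")
      lo <- min(keep); hi <- max(keep)
      drop_head <- sum(sc[seq_len(lo - 1L)] != "-")
      pc <- pc[lo:hi]; sc <- sc[lo:hi]
      both <- pc != "-" & sc != "-"
      ident <- if (any(both)) mean(pc[both] == sc[both]) else 0
      r_start <- 1L; r_end <- widths[i]
      t_start0 <- win_s0 + Biostrings::start(Biostrings::subject(pg)) - 1L +
        drop_head
      t_end0 <- t_start0 + sum(sc != "-")
      coverage <- (r_end - r_start + 1L) / widths[i]
      if (ident >= min_identity && coverage >= min_coverage) {
        al <- list(pc = pc, sc = sc, r_start = r_start, r_end = r_end,
                   t_start0 = t_start0, t_end0 = t_end0)
        if (i > 1L) {
          al <- refine_boundary(al, genomic, ref_ex, side = "start",
                                expected = "AG", refine_bp = refine_bp)
        }
        if (i < n_ex) {
          al <- refine_boundary(al, genomic, ref_ex, side = "end",
                                expected = model$donor_dialect[i],
                                refine_bp = refine_bp)
        }
        both <- al$pc != "-" & al$sc != "-"
        rec$ref_aligned <- paste(al$pc, collapse = "")
        rec$tgt_aligned <- paste(al$sc, collapse = "")
        rec$tgt_interval <- c(al$t_start0, al$t_end0)
        rec$ref_span <- c(al$r_start, al$r_end)
        rec$identity <- if (any(both)) mean(al$pc[both] == al$sc[both]) else 0
        rec$missing_data <- FALSE
        if (i > 1L && al$t_start0 >= 2L) {
          rec$acceptor_obs <- substr(genomic, al$t_start0 - 1L, al$t_start0)
        }
        if (i < n_ex && al$t_end0 + 2L <= nchar(genomic)) {
          rec$donor_obs <- substr(genomic, al$t_end0 + 1L, al$t_end0 + 2L)
        }
        cursor <- al$t_end0
      }
    }
    out[[i]] <- structure(rec, class = "exon_alignment")
  }
  if (all(vapply(out, function(r) r$missing_data, logical(1)))) {
    stop("locus not found: no exon of ", model$gene_id,
         " could be mapped onto the slice")
  }
  out
}

# shift one exon boundary by up to refine_bp bases towards splice-dialect
# conformity; shifts must be content-compatible with the reference so that a
# mutated but correctly placed site is left untouched
refine_boundary <- function(al, genomic, ref_ex, side, expected, refine_bp) {
  L <- nchar(ref_ex)
  refc <- strsplit(ref_ex, "")[[1L]]
  dinuc_at <- function(t_start0, t_end0) {
    if (side == "start") {
      if (t_start0 < 2L) return(NA_character_)
      substr(genomic, t_start0 - 1L, t_start0)
    } else {
      if (t_end0 + 2L > nchar(genomic)) return(NA_character_)
      substr(genomic, t_end0 + 1L, t_end0 + 2L)
    }
  }
  cur <- dinuc_at(al$t_start0, al$t_end0)
  if (!is.na(cur) && cur == expected) return(al)
  offsets <- setdiff(order_by_abs(seq(-refine_bp, refine_bp)), 0L)
  for (o in offsets) {
    if (side == "start") {
      new_t <- al$t_start0 + o
      if (new_t < 0L || new_t >= al$t_end0) next
      if (o < 0L) {  # gain |o| bases at exon start: must match clipped ref head
        k <- -o
        if (al$r_start - k < 1L) next
        gained <- substr(genomic, new_t + 1L, al$t_start0)
        if (gained != paste(refc[(al$r_start - k):(al$r_start - 1L)], collapse = "")) next
      } else {       # drop o aligned columns: only if they were mismatches
        cols <- aligned_cols(al$pc, al$sc, head = TRUE, n = o)
        if (is.null(cols) || any(al$pc[cols] == al$sc[cols])) next
      }
      if (!identical(dinuc_at(new_t, al$t_end0), expected)) next
      al <- apply_shift(al, side, o, refc)
      return(al)
    } else {
      new_t <- al$t_end0 + o
      if (new_t <= al$t_start0 || new_t > nchar(genomic)) next
      if (o > 0L) {  # gain bases at exon end: must match clipped ref tail
        if (al$r_end + o > L) next
        gained <- substr(genomic, al$t_end0 + 1L, new_t)
        if (gained != paste(refc[(al$r_end + 1L):(al$r_end + o)], collapse = "")) next
      } else {
        cols <- aligned_cols(al$pc, al$sc, head = FALSE, n = -o)
        if (is.null(cols) || any(al$pc[cols] == al$sc[cols])) next
      }
      if (!identical(dinuc_at(al$t_start0, new_t), expected)) next
      al <- apply_shift(al, side, o, refc)
      return(al)
    }
  }
  al
}

order_by_abs <- function(x) x[order(abs(x), x)]

# indices of the first/last n columns where the subject is aligned (non-gap)
aligned_cols <- function(pc, sc, head, n) {
  idx <- which(sc != "-")
  if (length(idx) < n + 1L) return(NULL)
  if (head) idx[seq_len(n)] else idx[(length(idx) - n + 1L):length(idx)]
}

apply_shift <- function(al, side, o, refc) {
  if (side == "start") {
    if (o < 0L) {
      k <- -o
      al$pc <- c(refc[(al$r_start - k):(al$r_start - 1L)], al$pc)
      al$sc <- c(refc[(al$r_start - k):(al$r_start - 1L)], al$sc)
      al$r_start <- al$r_start - k
      al$t_start0 <- al$t_start0 - k
    } else {
      cols <- aligned_cols(al$pc, al$sc, head = TRUE, n = o)
      drop_ref <- sum(al$pc[seq_len(max(cols))] != "-")
      al$pc <- al$pc[-seq_len(max(cols))]
      al$sc <- al$sc[-seq_len(max(cols))]
      al$r_start <- al$r_start + drop_ref
      al$t_start0 <- al$t_start0 + o
    }
  } else {
    if (o > 0L) {
      al$pc <- c(al$pc, refc[(al$r_end + 1L):(al$r_end + o)])
      al$sc <- c(al$sc, refc[(al$r_end + 1L):(al$r_end + o)])
      al$r_end <- al$r_end + o
      al$t_end0 <- al$t_end0 + o
    } else {
      cols <- aligned_cols(al$pc, al$sc, head = FALSE, n = -o)
      keep <- seq_len(min(cols) - 1L)
      drop_ref <- sum(al$pc[-keep] != "-")
      al$pc <- al$pc[keep]
      al$sc <- al$sc[keep]
      al$r_end <- al$r_end - drop_ref
      al$t_end0 <- al$t_end0 + o
    }
  }
  al
}

#' Detect ORF-disrupting mutations from exon alignments
#'
#' Emits one event per premature stop codon (frame tracked through upstream
#' indels), per contiguous indel run, and per lost splice site (observed
#' acceptor different from AG, or observed donor outside the declared
#' dialect). Exons flagged `missing_data` contribute no events; unobserved
#' reference positions are treated as ambiguous (`N`) so that codons touching
#' them are skipped during stop detection. Reference coordinates are 1-based
#' CDS positions.
#'
#' @param alignments Result of [map_exons()] for the same model.
#' @param model The reference [gene_model()].
#' @param species Species the slice belongs to.
#' @param context_k Number of residues shown before a premature stop in its
#'   `stop_context` motif (motifs like DSLFX use 4).
#' @return `data.frame` of events; zero rows when the ORF is intact.
#' @export
detect_disruptions <- function(alignments, model, species = model$species,
                               context_k = 4L) {
  n_ex <- nrow(model$exons)
  stopifnot(length(alignments) == n_ex)
  widths <- model$exons[, 2L] - model$exons[, 1L]
  offs <- cumsum(c(0L, utils::head(widths, -1L)))
  refc_all <- strsplit(model$cds_seq, "")[[1L]]
  events <- list()

  # --- column walk over the whole CDS -------------------------------------
  ref_col <- character(0); tgt_col <- character(0); refpos_col <- integer(0)
  for (i in seq_len(n_ex)) {
    a <- alignments[[i]]
    exon_ref <- refc_all[(offs[i] + 1L):(offs[i] + widths[i])]
    if (a$missing_data) {
      ref_col <- c(ref_col, exon_ref)
      tgt_col <- c(tgt_col, rep("N", widths[i]))
      refpos_col <- c(refpos_col, offs[i] + seq_len(widths[i]))
      next
    }
    rs <- a$ref_span[1L]; re <- a$ref_span[2L]
    if (rs > 1L) {
      ref_col <- c(ref_col, exon_ref[seq_len(rs - 1L)])
      tgt_col <- c(tgt_col, rep("N", rs - 1L))
      refpos_col <- c(refpos_col, offs[i] + seq_len(rs - 1L))
    }
    pc <- strsplit(a$ref_aligned, "")[[1L]]
    sc <- strsplit(a$tgt_aligned, "")[[1L]]
    rp <- integer(length(pc))
    cnt <- offs[i] + rs - 1L
    for (k in seq_along(pc)) {
      if (pc[k] != "-") { cnt <- cnt + 1L; rp[k] <- cnt } else rp[k] <- NA_integer_
    }
    ref_col <- c(ref_col, pc); tgt_col <- c(tgt_col, sc); refpos_col <- c(refpos_col, rp)
    if (re < widths[i]) {
      ref_col <- c(ref_col, exon_ref[(re + 1L):widths[i]])
      tgt_col <- c(tgt_col, rep("N", widths[i] - re))
      refpos_col <- c(refpos_col, offs[i] + (re + 1L):widths[i])
    }
  }

  exon_of <- function(cds_pos) {
    if (is.na(cds_pos)) return(NA_integer_)
    max(which(offs < cds_pos))
  }
  add_event <- function(kind, cds_nt_pos, indel_len = 0L, frameshift = FALSE,
                        splice_site = NA_character_, observed_site = NA_character_,
                        stop_context = NA_character_, allele = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      species = species, gene_id = model$gene_id, kind = kind,
      exon_index = exon_of(cds_nt_pos), cds_nt_pos = cds_nt_pos,
      codon_index = if (is.na(cds_nt_pos)) NA_integer_ else codon_of_cds_pos(cds_nt_pos),
      indel_len = as.integer(indel_len), frameshift = frameshift,
      splice_site = splice_site, observed_site = observed_site,
      stop_context = stop_context, allele = allele,
      cluster_id = NA_character_, validation = "unvalidated",
      n_supporting_projects = 0L, stringsAsFactors = FALSE)
  }

  # --- indel runs ---------------------------------------------------------
  state <- "M"; run_start <- NA_integer_
  flush_run <- function(state, run_start, k_end) {
    cols <- run_start:k_end
    if (state == "D") {
      dels <- paste(ref_col[cols], collapse = "")
      pos <- refpos_col[cols][1L]
      add_event("deletion", pos, indel_len = length(cols),
                frameshift = (length(cols) %% 3L) != 0L, allele = dels)
    } else if (state == "I") {
      ins <- paste(tgt_col[cols], collapse = "")
      after <- refpos_col[seq_len(run_start - 1L)]
      pos <- if (any(!is.na(after))) max(after, na.rm = TRUE) + 1L else 1L
      add_event("insertion", min(pos, length(refc_all)), indel_len = length(cols),
                frameshift = (length(cols) %% 3L) != 0L, allele = ins)
    }
  }
  for (k in seq_along(ref_col)) {
    st <- if (tgt_col[k] == "-") "D" else if (ref_col[k] == "-") "I" else "M"
    if (st != state) {
      if (state %in% c("D", "I")) flush_run(state, run_start, k - 1L)
      state <- st; run_start <- k
    }
  }
  if (state %in% c("D", "I")) flush_run(state, run_start, length(ref_col))

  # --- premature stops (frame tracked through indels) ---------------------
  keep <- tgt_col != "-"
  tgt_nt <- tgt_col[keep]
  tgt_rp <- refpos_col[keep]
  n_cod <- length(tgt_nt) %/% 3L
  prot_len <- nchar(model$protein_seq)
  if (n_cod >= 1L) {
    tgt_aa <- character(n_cod)
    for (j in seq_len(n_cod)) {
      cod <- tgt_nt[(3L * j - 2L):(3L * j)]
      tgt_aa[j] <- if (any(!cod %in% NUC)) "X" else GENCODE_AA[paste(cod, collapse = "")]
    }
    for (j in which(tgt_aa == "*")) {
      rp <- tgt_rp[(3L * j - 2L):(3L * j)]
      pos <- if (any(!is.na(rp))) rp[!is.na(rp)][1L] else NA_integer_
      if (is.na(pos)) {
        before <- tgt_rp[seq_len(3L * j - 3L)]
        pos <- if (any(!is.na(before))) max(before, na.rm = TRUE) + 1L else 1L
      }
      if (codon_of_cds_pos(pos) >= prot_len + 1L) next
      ctx_start <- max(1L, j - context_k)
      ctx <- paste(tgt_aa[ctx_start:(j - 1L)], collapse = "")
      add_event("premature_stop", pos,
                stop_context = paste0(ctx, "X"),
                allele = paste(tgt_nt[(3L * j - 2L):(3L * j)], collapse = ""))
    }
  }

  # --- splice sites --------------------------------------------------------
  for (i in seq_len(n_ex - 1L)) {
    don <- alignments[[i]]
    acc <- alignments[[i + 1L]]
    if (!don$missing_data && !is.na(don$donor_obs) &&
        don$donor_obs != model$donor_dialect[i]) {
      add_event("splice_loss", offs[i] + widths[i], splice_site = "donor",
                observed_site = don$donor_obs, allele = don$donor_obs)
    }
    if (!acc$missing_data && !is.na(acc$acceptor_obs) && acc$acceptor_obs != "AG") {
      add_event("splice_loss", offs[i + 1L] + 1L, splice_site = "acceptor",
                observed_site = acc$acceptor_obs, allele = acc$acceptor_obs)
    }
  }

  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out[order(out$cds_nt_pos, out$kind), , drop = FALSE]
}

empty_events <- function() {
  data.frame(species = character(0), gene_id = character(0), kind = character(0),
             exon_index = integer(0), cds_nt_pos = integer(0),
             codon_index = integer(0), indel_len = integer(0),
             frameshift = logical(0), splice_site = character(0),
             observed_site = character(0), stop_context = character(0),
             allele = character(0), cluster_id = character(0),
             validation = character(0), n_supporting_projects = integer(0),
             stringsAsFactors = FALSE)
}

#' Amino-acid context preceding a premature stop
#'
#' Returns the `k` residues preceding the stop, concatenated with `"X"`,
#' left-truncated near the N-terminus (a stop at codon 2 with `k = 3` yields
#' a single residue plus `"X"`).
#'
#' @param protein Reference amino-acid string.
#' @param codon_index 1-based codon at which the stop is observed; may be
#'   `len(protein) + 1` (the natural terminus).
#' @param k Number of context residues requested.
#' @return Character motif such as `"DSLFX"`.
#' @export
stop_context <- function(protein, codon_index, k = 3L) {
  n <- nchar(protein)
  if (k < 1L) stop("k must be >= 1")
  if (codon_index < 1L || codon_index > n + 1L) {
    stop("codon_index ", codon_index, " out of range 1..", n + 1L)
  }
  from <- max(1L, codon_index - k)
  paste0(substr(protein, from, codon_index - 1L), "X")
}

#' Validate disruption events against read evidence
#'
#' An event is `validated_fixed` when at least two independent projects each
#' show `min_reads` or more disrupted reads and no project anywhere shows an
#' intact read; `validated_polymorphic` when one project shows `min_reads` or
#' more reads of both alleles, or different projects are fixed for different
#' alleles; otherwise `unvalidated`. `n_supporting_projects` counts projects
#' with `min_reads` or more disrupted reads.
#'
#' @param events Event `data.frame` from [detect_disruptions()] or fixtures.
#' @param evidence `data.frame` with columns `project_id`, `species`,
#'   `event_key`, `reads_disrupted`, `reads_intact`.
#' @param min_reads Minimum reads per allele per project (default 3).
#' @return `events` with `validation` and `n_supporting_projects` filled in.
#' @export
validate_events <- function(events, evidence, min_reads = 3L) {
  stopifnot(min_reads >= 1L)
  if (nrow(events) == 0L) return(events)
  keys <- event_key(events)
  if (nrow(evidence)) {
    unknown <- setdiff(unique(evidence$event_key), keys)
    if (length(unknown)) {
      stop("evidence references unknown event key(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(evidence$reads_disrupted < 0) || any(evidence$reads_intact < 0)) {
      stop("read counts must be non-negative")
    }
  }
  for (r in seq_len(nrow(events))) {
    ev <- evidence[evidence$event_key == keys[r], , drop = FALSE]
    events$n_supporting_projects[r] <- sum(ev$reads_disrupted >= min_reads)
    events$validation[r] <- classify_evidence(ev, min_reads)
  }
  events
}

classify_evidence <- function(ev, min_reads) {
  if (!nrow(ev)) return("unvalidated")
  both <- ev$reads_disrupted >= min_reads & ev$reads_intact >= min_reads
  fixed_dis <- ev$reads_disrupted >= min_reads & ev$reads_intact == 0L
  fixed_int <- ev$reads_intact >= min_reads & ev$reads_disrupted == 0L
  if (any(both) || (any(fixed_dis) && any(fixed_int))) return("validated_polymorphic")
  if (sum(fixed_dis) >= 2L && all(ev$reads_intact == 0L)) return("validated_fixed")
  "unvalidated"
}

#' Canonical event key used to join events with read evidence
#' @param events Event `data.frame`.
#' @return Character vector of keys.
#' @export
event_key <- function(events) {
  paste(events$species, events$gene_id, events$kind, events$cds_nt_pos, sep = ":")
}

#' Classify the coding status of a gene in one species
#'
#' `coding` when coverage is complete and no event disrupts the frame;
#' `pseudogene` when at least one disrupting event is `validated_fixed`;
#' `polymorphic_pseudogene` when at least one disrupting event is
#' `validated_polymorphic` and none is fixed; `unresolved` otherwise (only
#' unvalidated disrupting events, or no events with incomplete coverage).
#' Disrupting events are premature stops, splice losses, and frameshifting
#' indels; in-frame indels are treated as non-disrupting.
#'
#' @param events Validated event `data.frame` for one species.
#' @param coverage_complete Was the whole ORF observed?
#' @param species,gene_id Identifiers (defaulted from `events` when present).
#' @return A `gene_status_call` list: `species`, `gene_id`, `status`,
#'   `events`.
#' @export
call_status <- function(events, coverage_complete,
                        species = if (nrow(events)) events$species[1L] else NA_character_,
                        gene_id = if (nrow(events)) events$gene_id[1L] else NA_character_) {
  disrupting <- events$kind %in% c("premature_stop", "splice_loss") | events$frameshift
  dis <- events[disrupting, , drop = FALSE]
  status <- if (nrow(dis) == 0L) {
    if (coverage_complete) "coding" else "unresolved"
  } else if (any(dis$validation == "validated_fixed")) {
    "pseudogene"
  } else if (any(dis$validation == "validated_polymorphic")) {
    "polymorphic_pseudogene"
  } else {
    "unresolved"
  }
  structure(list(species = species, gene_id = gene_id, status = status,
                 events = events), class = "gene_status_call")
}

#' @export
print.gene_status_call <- function(x, ...) {
  cat(sprintf("%s / %s: %s (%d events)\n", x$species, x$gene_id, x$status,
              nrow(x$events)))
  invisible(x)
}
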