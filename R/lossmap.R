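# Clustering of identical disruptions across species and minimum
# independent loss-event inference on a labelled species tree.

#' Cluster identical disruptions shared across species
#'
#' Two events fall in the same cluster iff they have the same kind, the same
#' homologous reference coordinate (`cds_nt_pos`), and the same allele (stop
#' codon identity, or indel length plus the inserted/deleted string, or the
#' observed splice dinucleotide). Singleton clusters are allowed.
#'
#' @param events Event `data.frame` with at least `species`, `kind`,
#'   `cds_nt_pos`, `allele` (and optionally `indel_len`).
#' @return `data.frame` with one row per cluster: `cluster_id`, `kind`,
#'   `cds_nt_pos`, `allele`, `n_members`, and a list-column
#'   `member_species`.
#' @export
cluster_shared <- function(events) {
  if (!nrow(events)) {
    return(data.frame(cluster_id = character(0), kind = character(0),
                      cds_nt_pos = integer(0), allele = character(0),
                      n_members = integer(0),
                      member_species = I(list()), stringsAsFactors = FALSE))
  }
  len <- if ("indel_len" %in% names(events)) events$indel_len else 0L
  key <- paste(events$kind, events$cds_nt_pos, len, events$allele, sep = "|")
  ord <- order(events$cds_nt_pos, events$kind, events$allele)
  ukey <- unique(key[ord])
  id_of <- stats::setNames(sprintf("C%02d", seq_along(ukey)), ukey)
  rows <- lapply(seq_along(ukey), function(k) {
    sel <- key == ukey[k]
    data.frame(cluster_id = id_of[[ukey[k]]], kind = events$kind[sel][1L],
               cds_nt_pos = events$cds_nt_pos[sel][1L],
               allele = events$allele[sel][1L],
               n_members = length(unique(events$species[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$member_species <- I(lapply(seq_along(ukey), function(k) {
    unique(events$species[key == ukey[k]])
  }))
  rownames(out) <- NULL
  out
}

#' Count minimum independent gene-loss events on a species tree
#'
#' Inactivated tips (status `pseudogene`, plus `polymorphic_pseudogene` when
#' `include_polymorphic = TRUE`) are joined by an edge whenever they share at
#' least one disruption cluster; each connected component is one loss event,
#' placed on the edge above the MRCA of its members. This deliberately counts
#' from shared-disruption identity rather than plain presence/absence (Dollo)
#' parsimony, so adjacent lineages inactivated by distinct mutations (for
#' example elephant and manatee) remain separate events; plain Dollo counting
#' is available via `method = "dollo"` for comparison. A warning entry is
#' recorded for every coding tip found inside an event's MRCA clade.
#'
#' @param tree A [species_tree()] or `phylo` object.
#' @param statuses Either a list of `gene_status_call`s or a `data.frame`
#'   with columns `species`, `status`.
#' @param clusters Result of [cluster_shared()].
#' @param include_polymorphic Count polymorphic pseudogenes as inactivated?
#' @param method `"shared"` (default) or `"dollo"`.
#' @return A `loss_event_set`: list with `events` (data.frame: `event_id`,
#'   `mrca_node`, `edge_row`, `n_tips`, plus list-columns `tips` and
#'   `clusters`), `n_events`, and `warnings`.
#' @export
count_loss_events <- function(tree, statuses, clusters = NULL,
                              include_polymorphic = FALSE,
                              method = c("shared", "dollo")) {
  method <- match.arg(method)
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  if (is.data.frame(statuses)) {
    st <- statuses
  } else {
    st <- data.frame(species = vapply(statuses, `[[`, character(1), "species"),
                     status = vapply(statuses, `[[`, character(1), "status"),
                     stringsAsFactors = FALSE)
  }
  wanted <- c("pseudogene", if (include_polymorphic) "polymorphic_pseudogene")
  inact <- unique(st$species[st$status %in% wanted])
  coding <- unique(st$species[st$status == "coding"])
  absent <- setdiff(inact, phy$tip.label)
  if (length(absent)) {
    stop("inactivated species absent from tree: ", paste(absent, collapse = ", "))
  }
  if (!length(inact)) {
    ev <- data.frame(event_id = character(0), mrca_node = integer(0),
                     edge_row = integer(0), n_tips = integer(0),
                     stringsAsFactors = FALSE)
    ev$tips <- I(list()); ev$clusters <- I(list())
    return(structure(list(events = ev, n_events = 0L, warnings = character(0)),
                     class = "loss_event_set"))
  }

  groups <- if (method == "shared") {
    shared_components(inact, clusters)
  } else {
    dollo_components(phy, inact)
  }

  warnings <- character(0)
  rows <- list(); tip_sets <- list(); clus_sets <- list()
  for (g in seq_along(groups)) {
    tips <- groups[[g]]
    idx <- match(tips, phy$tip.label)
    node <- if (length(idx) > 1L) ape::getMRCA(phy, idx) else idx
    edge_row <- which(phy$edge[, 2L] == node)
    if (!length(edge_row)) edge_row <- NA_integer_  # event at the root
    clade_tips <- phy$tip.label[clade_tip_indices(phy, node)]
    bad <- intersect(clade_tips, coding)
    if (length(bad)) {
      warnings <- c(warnings, sprintf(
        "event %d: coding tip(s) %s inside the event clade (Dollo violation)",
        g, paste(bad, collapse = ", ")))
    }
    extra <- setdiff(intersect(clade_tips, inact), tips)
    if (length(extra)) {
      warnings <- c(warnings, sprintf(
        "event %d: clade also contains inactivated tips from other events (homoplasy?): %s",
        g, paste(extra, collapse = ", ")))
    }
    supp <- character(0)
    if (!is.null(clusters) && nrow(clusters)) {
      supp <- clusters$cluster_id[vapply(clusters$member_species, function(m) {
        any(m %in% tips)
      }, logical(1))]
    }
    rows[[g]] <- data.frame(event_id = sprintf("E%02d", g), mrca_node = node,
                            edge_row = edge_row, n_tips = length(tips),
                            stringsAsFactors = FALSE)
    tip_sets[[g]] <- tips
    clus_sets[[g]] <- supp
  }
  ev <- do.call(rbind, rows)
  ev$tips <- I(tip_sets)
  ev$clusters <- I(clus_sets)
  structure(list(events = ev, n_events = nrow(ev), warnings = warnings),
            class = "loss_event_set")
}

#' @export
print.loss_event_set <- function(x, ...) {
  cat("loss_event_set:", x$n_events, "independent loss events\n")
  for (g in seq_len(nrow(x$events))) {
    cat(sprintf("  %s (%d tips): %s\n", x$events$event_id[g],
                x$events$n_tips[g],
                paste(x$events$tips[[g]], collapse = ", ")))
  }
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

# connected components of the tip graph whose edges are shared clusters
shared_components <- function(inact, clusters) {
  parent <- stats::setNames(seq_along(inact), inact)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  if (!is.null(clusters) && nrow(clusters)) {
    for (k in seq_len(nrow(clusters))) {
      mem <- intersect(clusters$member_species[[k]], inact)
      if (length(mem) > 1L) {
        for (m in mem[-1L]) union2(match(mem[1L], inact), match(m, inact))
      }
    }
  }
  roots <- vapply(seq_along(inact), find, integer(1))
  unname(split(inact, roots))
}

# maximal all-inactivated clades (classic Dollo loss counting)
dollo_components <- function(phy, inact) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  all_inact <- logical(nnode)
  all_inact[seq_len(ntip)] <- phy$tip.label %in% inact
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  node_ok <- function(n) {
    if (n <= ntip) return(all_inact[n])
    all(vapply(kids[[as.character(n)]], node_ok, logical(1)))
  }
  # maximal nodes: inactive-complete node whose parent is not
  parent_of <- stats::setNames(phy$edge[, 1L], phy$edge[, 2L])
  groups <- list()
  seen <- rep(FALSE, nnode)
  for (tipname in inact) {
    i <- match(tipname, phy$tip.label)
    if (seen[i]) next
    n <- i
    repeat {
      p <- parent_of[as.character(n)]
      if (is.na(p) || !node_ok(p)) break
      n <- p
    }
    tips_idx <- clade_tip_indices(phy, n)
    seen[tips_idx] <- TRUE
    groups[[length(groups) + 1L]] <- phy$tip.label[tips_idx]
  }
  groups
}
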