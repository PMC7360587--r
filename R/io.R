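#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that adds structural
#' checks with line numbers and normalises sequences to upper case. IUPAC
#' ambiguity codes are preserved, record order is preserved, and identifiers
#' are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping identifier to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("FASTA parse error in ", path, ": no '>' header found")
  pre <- which(nzchar(trimws(lines)) & !hdr)
  first_hdr <- which(hdr)[1L]
  if (length(pre) && pre[1L] < first_hdr) {
    stop(sprintf("FASTA parse error at line %d: sequence data before first header",
                 pre[1L]))
  }
  at <- which(hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[at]))
  if (any(!nzchar(ids))) {
    stop(sprintf("FASTA parse error at line %d: empty header", at[!nzchar(ids)][1L]))
  }
  ends <- c(at[-1L] - 1L, length(lines))
  for (k in seq_along(at)) {
    body <- if (ends[k] > at[k]) lines[(at[k] + 1L):ends[k]] else character(0)
    if (!length(body) || !any(nzchar(gsub("\\s", "", body)))) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                   at[k], ids[k]))
    }
  }
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a species tree with clade and branch labels
#'
#' Reads a Newick tree and a YAML label file mapping clade labels to tip sets
#' and branch labels to the stem edge above the MRCA of a tip set. Each clade
#' label must be monophyletic; clade labels designate the edges *inside* the
#' clade (below its MRCA) while branch labels designate the single stem edge
#' above an MRCA, so the two never overlap for a clade and its own stem.
#'
#' @param newick_path Path to a Newick file.
#' @param labels_path Path to a YAML file with top-level keys `clades`
#'   (label -> character vector of tips) and optional `branches`
#'   (label -> character vector of tips whose MRCA stem edge is labelled).
#' @return A `species_tree` object: list with elements `phylo` (the
#'   [ape::read.tree()] tree), `clades`, `clade_edges`, `branch_edges`
#'   (edge row indices into `phylo$edge`), and `labels`.
#' @export
read_labeled_tree <- function(newick_path, labels_path = NULL) {
  phy <- ape::read.tree(newick_path)
  if (is.null(phy)) stop("could not parse Newick file: ", newick_path)
  labels <- if (is.null(labels_path)) list() else yaml::read_yaml(labels_path)
  species_tree(phy, clades = labels$clades, branches = labels$branches)
}

#' Construct a labelled species tree
#'
#' @param phy A rooted `phylo` object.
#' @param clades Named list: clade label -> character vector of tip labels.
#' @param branches Named list: branch label -> character vector of tips; the
#'   labelled edge is the stem above their MRCA.
#' @return A `species_tree` object.
#' @export
species_tree <- function(phy, clades = NULL, branches = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  clades <- clades %||% list()
  branches <- branches %||% list()
  tip <- phy$tip.label
  clade_edges <- list()
  for (lab in names(clades)) {
    tips <- clades[[lab]]
    missing <- setdiff(tips, tip)
    if (length(missing)) {
      stop("clade ", lab, " references unknown tips: ", paste(missing, collapse = ", "))
    }
    if (length(tips) > 1L) {
      node <- ape::getMRCA(phy, tips)
      below <- tip[clade_tip_indices(phy, node)]
      if (!setequal(below, tips)) {
        stop("clade label ", lab, " is not monophyletic; MRCA also contains: ",
             paste(setdiff(below, tips), collapse = ", "))
      }
      clade_edges[[lab]] <- clade_edge_rows(phy, node)
    } else {
      clade_edges[[lab]] <- which(phy$edge[, 2L] == match(tips, tip))
    }
  }
  branch_edges <- integer(0)
  for (lab in names(branches)) {
    tips <- branches[[lab]]
    missing <- setdiff(tips, tip)
    if (length(missing)) {
      stop("branch ", lab, " references unknown tips: ", paste(missing, collapse = ", "))
    }
    node <- if (length(tips) > 1L) ape::getMRCA(phy, tips) else match(tips, tip)
    row <- which(phy$edge[, 2L] == node)
    if (!length(row)) stop("branch label ", lab, " maps to the root; no stem edge exists")
    branch_edges[lab] <- row
  }
  all_lab <- c(clade_edges, as.list(branch_edges))
  if (length(all_lab) > 1L) {
    ed <- unlist(all_lab, use.names = FALSE)
    if (anyDuplicated(ed)) {
      dup <- ed[duplicated(ed)][1L]
      owners <- names(all_lab)[vapply(all_lab, function(e) dup %in% e, logical(1))]
      stop("edge assigned to more than one label: ", paste(owners, collapse = ", "))
    }
  }
  structure(list(phylo = phy, clades = clades, clade_edges = clade_edges,
                 branch_edges = branch_edges,
                 labels = c(names(clades), names(branches))),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$phylo$tip.label), "tips,",
      length(x$clades), "clade labels,", length(x$branch_edges), "branch labels\n")
  invisible(x)
}

# tip indices below an internal node (node itself if a tip)
clade_tip_indices <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  while (length(stack)) {
    n <- stack[[1L]]; stack <- stack[-1L]
    ch <- kids[[as.character(n)]]
    is_tip <- ch <= ntip
    out <- c(out, ch[is_tip])
    stack <- c(stack, ch[!is_tip])
  }
  sort(out)
}

# edge rows strictly inside the clade rooted at `node` (excludes stem)
clade_edge_rows <- function(phy, node) {
  ntip <- length(phy$tip.label)
  inside <- node
  repeat {
    more <- phy$edge[phy$edge[, 1L] %in% inside, 2L]
    new <- setdiff(more, inside)
    if (!length(new)) break
    inside <- c(inside, new)
  }
  which(phy$edge[, 1L] %in% inside)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
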