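# Packaged in-study fixtures: the cross-species disruption matrix, the
# labelled mammal tree, the human population variant table, and the
# 14-model ladder. Where the published material names an architecture but
# not a value (exact stop alleles, sparse table cells, motif letters), the
# fixture records a synthetic reconstruction; see the package vignette.

#' Load the packaged fixture bundle
#'
#' Returns the cross-species GBA3 disruption matrix (one record per mutation
#' square, with shared-cluster identities), the labelled species tree, the
#' human 1KGP-style variant table for GBA3 and GBA, the default model
#' ladder, and the missing-data intervals. All bundle invariants (species on
#' the tree, ladder labels defined, identical events within clusters) are
#' checked on load.
#'
#' @return A `fixture_bundle` list: `disruptions`, `missing_data`, `tree`,
#'   `variants`, `model_ladder`.
#' @export
load_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "geneloss")
  disruptions <- utils::read.delim(ext("gba3_disruptions.tsv"),
                                   stringsAsFactors = FALSE)
  missing_data <- utils::read.delim(ext("gba3_missing_data.tsv"),
                                    stringsAsFactors = FALSE)
  tree <- read_labeled_tree(ext("mammal_tree.nwk"), ext("clade_labels.yaml"))
  variants <- utils::read.delim(ext("variants_1kgp.tsv"),
                                stringsAsFactors = FALSE)
  ladder <- default_model_ladder()

  tips <- tree$phylo$tip.label
  off_tree <- setdiff(unique(disruptions$species), tips)
  if (length(off_tree)) {
    stop("fixture inconsistency: species not on the tree: ",
         paste(off_tree, collapse = ", "))
  }
  for (id in unique(disruptions$cluster_id)) {
    rows <- disruptions[disruptions$cluster_id == id, , drop = FALSE]
    if (nrow(unique(rows[, c("kind", "cds_nt_pos", "indel_len", "allele")])) != 1L) {
      stop("fixture inconsistency: cluster ", id, " members differ")
    }
  }
  defined <- c(names(tree$clade_edges), names(tree$branch_edges))
  for (m in names(ladder$models)) {
    labs <- unlist(ladder$models[[m]], use.names = FALSE)
    if (length(setdiff(labs, defined))) {
      stop("ladder model ", m, " references undefined labels: ",
           paste(setdiff(labs, defined), collapse = ", "))
    }
  }
  structure(list(disruptions = disruptions, missing_data = missing_data,
                 tree = tree, variants = variants, model_ladder = ladder),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle:",
      nrow(x$disruptions), "disruption records in",
      length(unique(x$disruptions$species)), "species;",
      nrow(x$variants), "variants;",
      length(x$model_ladder$models), "ladder models\n")
  invisible(x)
}

#' Gene-status calls for every fixture species
#'
#' Applies [call_status()] per species to the fixture disruption records;
#' tree tips without any recorded disruption are called `coding` (their
#' coverage was complete in the source material).
#'
#' @param bundle A [load_fixtures()] bundle.
#' @return `data.frame` with `species`, `status`.
#' @export
fixture_statuses <- function(bundle) {
  tips <- bundle$tree$phylo$tip.label
  rows <- lapply(tips, function(sp) {
    ev <- bundle$disruptions[bundle$disruptions$species == sp, , drop = FALSE]
    covered <- !sp %in% bundle$missing_data$species
    call <- call_status(ev, coverage_complete = covered, species = sp,
                        gene_id = "GBA3")
    data.frame(species = sp, status = call$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shared-disruption clusters of the fixture matrix
#'
#' @param bundle A [load_fixtures()] bundle.
#' @return Cluster `data.frame` in the form of [cluster_shared()], using the
#'   fixture's recorded cluster identities.
#' @export
fixture_clusters <- function(bundle) {
  d <- bundle$disruptions
  ids <- unique(d$cluster_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- d[d$cluster_id == id, , drop = FALSE]
    data.frame(cluster_id = id, kind = rows$kind[1L],
               cds_nt_pos = rows$cds_nt_pos[1L], allele = rows$allele[1L],
               n_members = length(unique(rows$species)),
               stringsAsFactors = FALSE)
  }))
  out$member_species <- I(lapply(ids, function(id) {
    unique(d$species[d$cluster_id == id])
  }))
  rownames(out) <- NULL
  out
}
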