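# Genetic-code tables and deterministic RNG helpers shared across modules.

GENCODE_AA <- {
  gc <- Biostrings::GENETIC_CODE
  out <- as.character(gc)
  names(out) <- names(gc)
  out
}

STOP_CODONS <- names(GENCODE_AA)[GENCODE_AA == "*"]

#' The 61 sense codons, alphabetical order
#' @format Character vector of length 61.
#' @keywords internal
SENSE_CODONS <- sort(setdiff(names(GENCODE_AA), STOP_CODONS))

NUC <- c("A", "C", "G", "T")

# ordered pairs of sense codons differing at exactly one position, with
# transition / nonsynonymous flags; backbone of the codon rate matrix
CODON_PAIRS <- local({
  n <- length(SENSE_CODONS)
  mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  res <- list()
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2L, mat[i, ], FUN = "!=")
    nd <- rowSums(diffs)
    js <- which(nd == 1L)
    if (!length(js)) next
    pos <- apply(diffs[js, , drop = FALSE], 1L, which)
    from <- mat[cbind(i, pos)]
    to <- mat[cbind(js, pos)]
    res[[i]] <- cbind(i = i, j = js,
                      ts = as.integer(is_ts(from, to)),
                      nonsyn = as.integer(GENCODE_AA[SENSE_CODONS[i]] !=
                                            GENCODE_AA[SENSE_CODONS[js]]))
  }
  do.call(rbind, res)
})

#' Derive a deterministic substream seed
#'
#' Fans a single run seed out into per-component seeds so that adding one
#' generator call never perturbs another component's stream. Result is always
#' a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param index Integer substream index.
#' @return Integer seed below 2^31.
#' @export
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(index) * 8191 + 1) %%
               2147483647)
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so library code never disturbs a
#' caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# private uniform stream: function(n) -> n uniforms, isolated from the
# global RNG
make_rng <- function(seed) {
  state <- NULL
  seed <- as.integer(as.double(seed) %% 2147483647)
  function(n) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    u <- stats::runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    u
  }
}
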