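#' Construct a reference gene model
#'
#' A gene model bundles the exon structure and the reference coding sequence
#' of a single gene. Coordinates are 0-based half-open internally; reports and
#' HGVS-style labels (c.1368, p.Y456X) are 1-based. The reference CDS excludes
#' the terminal stop codon, so a 1407 bp ORF encodes a 469 residue protein.
#'
#' @param gene_id,species,contig_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of genomic `(start, end)`
#'   intervals, 0-based half-open, sorted and non-overlapping, in CDS order.
#' @param cds_seq Reference coding nucleotide sequence (CDS orientation).
#' @param donor_dialect Character vector of expected donor dinucleotides, one
#'   per intron, each `"GT"` or `"GC"`. Acceptors are always `"AG"`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, species, contig_id, strand = "+", exons,
                       cds_seq, donor_dialect = NULL) {
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2L] <= exons[, 1L])) stop("exon with non-positive length")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1L], strictly = TRUE)) stop("exons must be sorted by start")
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) stop("exons overlap")
  }
  cds_seq <- toupper(cds_seq)
  widths <- exons[, 2L] - exons[, 1L]
  if (nchar(cds_seq) != sum(widths)) {
    stop("CDS length (", nchar(cds_seq), ") does not equal total exon length (",
         sum(widths), ")")
  }
  if (nchar(cds_seq) %% 3L != 0L) {
    stop("reference CDS length ", nchar(cds_seq), " is not a multiple of 3")
  }
  protein <- translate_cds(cds_seq)
  if (grepl("\\*", substr(protein, 1L, nchar(protein)))) {
    stop("reference CDS contains an internal stop codon at codon ",
         regexpr("\\*", protein))
  }
  n_intron <- nrow(exons) - 1L
  donor_dialect <- donor_dialect %||% rep("GT", n_intron)
  if (length(donor_dialect) != n_intron || !all(donor_dialect %in% c("GT", "GC"))) {
    stop("donor_dialect must give GT or GC for each of the ", n_intron, " introns")
  }
  structure(list(gene_id = gene_id, species = species, contig_id = contig_id,
                 strand = strand, exons = exons,
                 donor_dialect = donor_dialect,
                 acceptor_dialect = rep("AG", n_intron),
                 cds_seq = cds_seq, protein_seq = protein),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s): %d exons, ORF %d bp, protein %d aa\n",
              x$gene_id, x$species, nrow(x$exons), nchar(x$cds_seq),
              nchar(x$protein_seq)))
  invisible(x)
}

#' Read a gene model from GFF3 + FASTA
#'
#' Exon features are taken from the GFF3 file (one gene), the contig sequence
#' from the FASTA. Minus-strand genes are returned in CDS orientation (exons
#' listed 5'->3' on the coding strand, CDS reverse-complemented). A per-intron
#' donor dialect may be declared with a `donor_dialect` attribute (`GT` or
#' `GC`) on the exon preceding the intron; the default is `GT`.
#'
#' @param gff_path GFF3 file with `exon` features for one gene.
#' @param fasta_path FASTA file containing the contig.
#' @param gene_id Optional gene identifier; defaults to the GFF3 `gene_id`
#'   attribute or the file stem.
#' @param species Species name recorded on the model.
#' @return A [gene_model()] object.
#' @export
read_gene_model <- function(gff_path, fasta_path, gene_id = NULL,
                            species = "reference") {
  gr <- rtracklayer::import(gff_path)
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) stop("no exon features in ", gff_path)
  ex <- ex[order(GenomicRanges::start(ex))]
  contig <- as.character(GenomicRanges::seqnames(ex)[1L])
  strand <- as.character(GenomicRanges::strand(ex)[1L])
  if (strand == "*") strand <- "+"
  seqs <- read_fasta(fasta_path)
  if (!contig %in% names(seqs)) stop("contig ", contig, " not found in ", fasta_path)
  genome <- seqs[[contig]]
  # GFF3 is 1-based closed; convert to 0-based half-open
  starts <- GenomicRanges::start(ex) - 1L
  ends <- GenomicRanges::end(ex)
  chunks <- substring(genome, starts + 1L, ends)
  cds <- paste(chunks, collapse = "")
  dial <- rep("GT", max(length(ex) - 1L, 0L))
  attr_dial <- if ("donor_dialect" %in% names(GenomicRanges::mcols(ex))) {
    as.character(GenomicRanges::mcols(ex)$donor_dialect)
  } else rep(NA_character_, length(ex))
  if (strand == "-") {
    cds <- revcomp(cds)
    # exon order along CDS is reversed; dialect attributes follow CDS order
    attr_dial <- rev(attr_dial)
  }
  n_intron <- length(ex) - 1L
  if (n_intron > 0L) {
    d <- attr_dial[seq_len(n_intron)]
    dial <- ifelse(is.na(d), "GT", d)
  } else {
    dial <- character(0)
  }
  if (is.null(gene_id)) {
    gene_id <- GenomicRanges::mcols(ex)$gene_id[1L] %||%
      tools::file_path_sans_ext(basename(gff_path))
    if (is.na(gene_id)) gene_id <- tools::file_path_sans_ext(basename(gff_path))
  }
  gene_model(gene_id = gene_id, species = species, contig_id = contig,
             strand = strand, exons = cbind(starts, ends), cds_seq = cds,
             donor_dialect = dial)
}

#' Translate a CDS (no terminal stop expected)
#' @param cds Nucleotide string, length a multiple of 3. Codons containing
#'   characters outside ACGT translate to `"X"`.
#' @return Amino-acid string; stop codons appear as `"*"`.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3L == 0L)
  if (nchar(cds) == 0L) return("")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- GENCODE_AA[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Map a CDS nucleotide position to its codon number
#'
#' HGVS-style arithmetic: c.1368 lies in codon 456.
#'
#' @param cds_pos 1-based coding nucleotide position(s).
#' @return 1-based codon index (integer vector).
#' @export
codon_of_cds_pos <- function(cds_pos) {
  stopifnot(all(cds_pos >= 1L))
  as.integer((cds_pos - 1L) %/% 3L + 1L)
}

#' Protein length encoded by an ORF
#'
#' The ORF excludes the terminal stop codon: a 1407 bp ORF encodes 469
#' residues.
#'
#' @param orf_bp ORF length in base pairs (multiple of 3).
#' @return Protein length in residues.
#' @export
protein_length_of_orf <- function(orf_bp) {
  stopifnot(all(orf_bp %% 3L == 0L))
  as.integer(orf_bp %/% 3L)
}

#' Reverse-complement a nucleotide string
#' @param x Nucleotide string (IUPAC codes allowed).
#' @return Reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Synthetic reference gene model in the image of human GBA3
#'
#' Builds a deterministic synthetic 5-exon gene model with a 1407 bp ORF
#' (469 residues), a `GC` donor dialect on intron 2, a tyrosine codon (TAT) at
#' codon 456 (so the c.1368 T>A change creates the p.Y456X stop), and the
#' exon-3 amino-acid motifs DSLF (codons 240-243) and YTTR (codons 260-263)
#' after which premature stops are classically observed. The sequence itself
#' is synthetic: it shares the real gene's architecture, not its bases.
#'
#' @param gene_id,species Identifiers recorded on the model.
#' @return A [gene_model()] object.
#' @export
make_demo_gene_model <- function(gene_id = "GBA3", species = "Homo_sapiens") {
  exon_len <- c(297L, 285L, 330L, 258L, 237L)  # sums to 1407
  n_codon <- sum(exon_len) / 3L
  rng <- make_rng(760201L)
  sense <- SENSE_CODONS
  codons <- sense[ceiling(rng(n_codon) * length(sense))]
  set_aa <- function(codons, idx, aas) {
    pick <- vapply(aas, function(a) {
      opts <- sense[GENCODE_AA[sense] == a]
      opts[[1L]]
    }, character(1))
    codons[idx] <- pick
    codons
  }
  codons <- set_aa(codons, 240:243, c("D", "S", "L", "F"))
  codons <- set_aa(codons, 260:263, c("Y", "T", "T", "R"))
  codons[456L] <- "TAT"
  cds <- paste(codons, collapse = "")
  # genomic exon coordinates: abutting with 500 bp gaps (introns live in the
  # simulated slice, not in the model's contig arithmetic)
  starts <- cumsum(c(1000L, utils::head(exon_len, -1L) + 500L))
  exons <- cbind(starts, starts + exon_len)
  gene_model(gene_id = gene_id, species = species, contig_id = "chr4",
             strand = "+", exons = exons, cds_seq = cds,
             donor_dialect = c("GT", "GC", "GT", "GT"))
}
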