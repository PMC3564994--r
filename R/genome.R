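#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` (uppercase DNA).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences.
#' All package coordinates are 0-based half-open.
#'
#' @param seqs Named character vector of DNA sequences.
#' @return A validated `genome` object.
#' @export
genome <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs)))
    stop("chromosome names must be present and unique")
  seqs <- toupper(unlist(seqs))
  if (any(nchar(seqs) < 1L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-IUPAC-DNA character in chromosome(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s)\n")
  for (nm in names(x)) cat(" ", nm, nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Extract a genome subsequence
#'
#' 0-based half-open interval; strand `"-"` returns the reverse complement
#' (transcript orientation).
#'
#' @param genome A [genome()] object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return The subsequence as a character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

#' Replace a genome segment in place
#'
#' `replacement` is given in the orientation of `strand` and is written
#' over the forward strand starting at `start` (0-based).
#'
#' @param genome A [genome()] object.
#' @param chrom Chromosome name.
#' @param start 0-based start of the replaced segment (forward strand).
#' @param strand Orientation of `replacement`.
#' @param replacement Sequence to write.
#' @return The edited genome.
#' @export
genome_replace <- function(genome, chrom, start, strand, replacement) {
  if (strand == "-") replacement <- revcomp(replacement)
  seqs <- unclass(genome)
  substr(seqs[[chrom]], start + 1L, start + nchar(replacement)) <- replacement
  structure(seqs, class = "genome")
}

chrom_len <- function(genome, chrom) nchar(genome[[chrom]])

#' Build a gene-model table
#'
#' Gene models are stored as a data.frame with 0-based half-open ORF
#' coordinates, a strand, a dubious flag and a list-column of intron
#' intervals (each a two-column matrix, also 0-based half-open).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end ORF interval, 0-based half-open.
#' @param introns List of two-column matrices (may be `NULL` entries).
#' @param dubious Logical flag per gene (default `FALSE`).
#' @return A `data.frame` of gene models.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       introns = NULL, dubious = FALSE) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (!all(strand %in% c("+", "-"))) stop("unknown strand symbol")
  if (any(end <= start)) stop("gene end must exceed start")
  if (is.null(introns)) introns <- rep(list(NULL), n)
  for (i in seq_len(n)) {
    iv <- introns[[i]]
    if (is.null(iv) || nrow(iv) == 0L) next
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] < start[i]) || any(iv[, 2L] > end[i]) ||
        any(iv[, 1L] <= start[i] & iv[, 2L] >= end[i]))
      stop("intron outside its gene: ", gene_id[i])
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop("overlapping introns: ", gene_id[i])
    introns[[i]] <- iv
  }
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = start, end = end,
                   dubious = rep_len(dubious, n),
                   stringsAsFactors = FALSE)
  df$introns <- introns
  df
}

# spliced ORF length (intron bases removed)
orf_coding_length <- function(gene_row) {
  len <- gene_row$end - gene_row$start
  iv <- gene_row$introns[[1L]]
  if (!is.null(iv) && nrow(iv) > 0L) len <- len - sum(iv[, 2L] - iv[, 1L])
  len
}
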