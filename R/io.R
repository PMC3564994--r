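# All external formats are converted to the package's internal conventions at
# the boundary: coordinates 0-based half-open, sequences uppercase DNA, one
# coverage vector per chromosome per strand. GFF3 (1-based inclusive) is the
# only format needing coordinate conversion; bedGraph is already 0-based.

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return A [genome()] object; sequences uppercased, record order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) stop("duplicate record name in ", path)
  seqs <- as.character(ss)
  names(seqs) <- nms
  genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome()] object.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Recognises `gene` features (the ORF interval) and `intron` features
#' attached to a gene through their `Parent` attribute. GFF3 1-based
#' inclusive coordinates become 0-based half-open. A gene with attribute
#' `orf_classification=Dubious` is flagged dubious.
#'
#' @param path GFF3 file.
#' @param genome Optional [genome()] used to validate chromosome bounds.
#' @return Gene-model `data.frame` (see [gene_model()]).
#' @export
read_gff <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gg <- gr[type %in% c("gene", "CDS")]
  ii <- gr[type == "intron"]
  if (length(gg) == 0L) stop("no gene features in ", path)
  std <- as.character(BiocGenerics::strand(gg))
  if (any(!std %in% c("+", "-"))) stop("unknown strand symbol in ", path)
  ids <- gg$ID
  if (is.null(ids) || anyNA(ids)) stop("gene feature without ID attribute")
  dub <- if ("orf_classification" %in% names(S4Vectors::mcols(gg)))
    !is.na(gg$orf_classification) & gg$orf_classification == "Dubious"
  else rep(FALSE, length(gg))
  start0 <- BiocGenerics::start(gg) - 1L
  end0 <- BiocGenerics::end(gg)
  chroms <- as.character(GenomicRanges::seqnames(gg))
  if (!is.null(genome)) {
    lens <- vapply(chroms, function(ch) {
      if (is.null(genome[[ch]])) stop("gene on unknown chromosome ", ch)
      chrom_len(genome, ch)
    }, 0L)
    if (any(start0 < 0L) || any(end0 > lens))
      stop("gene feature outside chromosome bounds")
  }
  introns <- rep(list(NULL), length(gg))
  if (length(ii) > 0L) {
    par <- vapply(ii$Parent, function(p) p[[1L]], "")
    for (k in seq_along(ii)) {
      j <- match(par[k], ids)
      if (is.na(j)) stop("intron with unknown Parent: ", par[k])
      iv <- rbind(introns[[j]],
                  c(BiocGenerics::start(ii)[k] - 1L, BiocGenerics::end(ii)[k]))
      introns[[j]] <- iv
    }
  }
  gene_model(gene_id = ids, chrom = chroms, strand = std,
             start = start0, end = end0, introns = introns, dubious = dub)
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model `data.frame`.
#' @param path Output file.
#' @export
write_gff <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr1 <- sprintf("ID=%s%s", g$gene_id,
                     if (isTRUE(g$dubious)) ";orf_classification=Dubious" else "")
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tendscan\tgene\t%d\t%d\t.\t%s\t.\t%s",
      g$chrom, g$start + 1L, g$end, g$strand, attr1)
    iv <- g$introns[[1L]]
    if (!is.null(iv) && nrow(iv) > 0L) {
      for (k in seq_len(nrow(iv))) {
        rows[[length(rows) + 1L]] <- sprintf(
          "%s\tendscan\tintron\t%d\t%d\t.\t%s\t.\tID=%s_intron%d;Parent=%s",
          g$chrom, iv[k, 1L] + 1L, iv[k, 2L], g$strand, g$gene_id, k, g$gene_id)
      }
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read a bedGraph file into one strand of a coverage track
#'
#' bedGraph intervals are 0-based half-open; bases not covered by any
#' interval are zero.
#'
#' @param path bedGraph file (one strand of one condition).
#' @param genome A [genome()] giving chromosome lengths.
#' @param strand Which strand the file describes (`"+"` or `"-"`).
#' @param track Optional existing `cov_track` to fill into (for combining
#'   the two per-strand files of a condition).
#' @param condition Condition label for a newly created track.
#' @return A `cov_track`.
#' @export
read_bedgraph <- function(path, genome, strand = "+", track = NULL,
                          condition = "cond") {
  if (is.null(track)) track <- empty_track(genome, condition)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(track)
  f <- strsplit(lines, "[ \t]+")
  ch <- vapply(f, `[[`, "", 1L)
  s0 <- as.integer(vapply(f, `[[`, "", 2L))
  e0 <- as.integer(vapply(f, `[[`, "", 3L))
  val <- as.numeric(vapply(f, `[[`, "", 4L))
  if (any(val < 0)) stop("negative coverage value in ", path)
  for (cname in unique(ch)) {
    sel <- ch == cname
    v <- track$cov[[cname]][[strand]]
    if (is.null(v)) stop("unknown chromosome in bedGraph: ", cname)
    if (any(e0[sel] > length(v)) || any(s0[sel] < 0L))
      stop("bedGraph interval beyond chromosome end: ", cname)
    for (j in which(sel)) v[(s0[j] + 1L):e0[j]] <- val[j]
    track$cov[[cname]][[strand]] <- v
  }
  track
}

#' Write one strand of a coverage track as bedGraph
#'
#' Equal-value runs are merged into single intervals; zero runs are omitted.
#'
#' @param track A `cov_track`.
#' @param path Output file.
#' @param strand Strand to export.
#' @export
write_bedgraph <- function(track, path, strand = "+") {
  out <- character(0)
  for (cname in names(track$cov)) {
    v <- track$cov[[cname]][[strand]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      out <- c(out, sprintf("%s\t%d\t%d\t%s", cname, starts[keep], ends[keep],
                            format(r$values[keep], trim = TRUE, scientific = FALSE)))
  }
  writeLines(out, path)
  invisible(path)
}

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Read an RBP motif table
#'
#' Two-column TSV of motif id and IUPAC consensus. `U` letters are
#' normalized to `T` (DNA-space matching) and flagged `rna_origin`.
#'
#' @param path TSV file (no header; lines starting `#` ignored).
#' @return `data.frame` with `motif_id`, `consensus`, `rna_origin`.
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("motif file must have two tab-separated columns")
  consensus <- toupper(df[[2L]])
  letters_used <- strsplit(consensus, "")
  for (i in seq_along(letters_used)) {
    bad <- setdiff(letters_used[[i]], IUPAC_DNA)
    if (length(bad) > 0L)
      stop("illegal IUPAC letter '", bad[1L], "' in motif ", df[[1L]][i])
  }
  rna <- grepl("U", consensus, fixed = TRUE)
  data.frame(motif_id = as.character(df[[1L]]),
             consensus = gsub("U", "T", consensus, fixed = TRUE),
             rna_origin = rna, stringsAsFactors = FALSE)
}

#' Read a FASTQ file (sequences and ids only)
#'
#' Qualities are discarded: the end-calling method never uses them.
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences (uppercase).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write reads to FASTQ with placeholder qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}
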