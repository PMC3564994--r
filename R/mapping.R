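# Exact-match unique-placement mapper. A read maps iff its sequence occurs
# exactly once in the genome counting both strands; reads failing at full
# length are retried after trimming 4 bp from the 3' end, down to 28 bp.
# Internally the index stores forward-strand 28-mers only; minus-strand
# occurrences are answered by querying the reverse complement, which is
# equivalent to a both-strand index.

#' Build a unique-placement seed index
#'
#' @param genome A [genome()] object.
#' @param k Seed length (default 28, the shortest mappable read).
#' @return A `unique_index` object.
#' @export
build_index <- function(genome, k = 28L) {
  if (length(genome) == 0L) stop("empty genome")
  kmers <- character(0); chv <- character(0); posv <- integer(0)
  for (ch in names(genome)) {
    L <- chrom_len(genome, ch)
    if (L < k) next
    starts <- 0:(L - k)
    km <- substring(genome[[ch]], starts + 1L, starts + k)
    kmers <- c(kmers, km)
    chv <- c(chv, rep(ch, length(km)))
    posv <- c(posv, starts)
  }
  ok <- !grepl("N", kmers, fixed = TRUE)  # seeds containing N never match
  kmers <- kmers[ok]; chv <- chv[ok]; posv <- posv[ok]
  uk <- unique(kmers)
  id <- match(kmers, uk)
  occ <- split(seq_along(kmers), factor(id, levels = seq_along(uk)))
  structure(list(k = k, kmers = uk, occ = occ, chrom = chv, pos = posv),
            class = "unique_index")
}

#' Query all occurrences of a k-mer on either strand
#'
#' Minus-strand occurrences are reported at the forward coordinate of the
#' occurrence start.
#'
#' @param index A `unique_index`.
#' @param kmer Query of exactly the index seed length.
#' @return `data.frame` with `chrom`, `strand`, `pos` (0-based).
#' @export
query_index <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("query length must equal index k")
  hit <- function(q, strand) {
    j <- match(q, index$kmers)
    if (is.na(j)) return(NULL)
    rows <- index$occ[[j]]
    data.frame(chrom = index$chrom[rows], strand = strand,
               pos = index$pos[rows], stringsAsFactors = FALSE)
  }
  fwd <- hit(kmer, "+")
  rc <- revcomp(kmer)
  rev <- if (identical(rc, kmer)) NULL else hit(rc, "-")
  if (identical(rc, kmer) && !is.null(fwd)) {
    # revcomp-palindromic seed: each locus is an occurrence on both strands
    rev <- fwd; rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (is.null(out))
    data.frame(chrom = character(0), strand = character(0),
               pos = integer(0), stringsAsFactors = FALSE)
  else out
}

# forward-strand placements of `seq` verified to full length
placements_fwd <- function(index, genome, seq) {
  len <- nchar(seq)
  seed <- substr(seq, 1L, index$k)
  j <- match(seed, index$kmers)
  if (is.na(j)) return(NULL)
  rows <- index$occ[[j]]
  ch <- index$chrom[rows]; p <- index$pos[rows]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (p[i] + len > chrom_len(genome, ch[i])) next
    keep[i] <- substr(genome[[ch[i]]], p[i] + 1L, p[i] + len) == seq
  }
  if (!any(keep)) return(NULL)
  data.frame(chrom = ch[keep], pos = p[keep], stringsAsFactors = FALSE)
}

#' Map a read requiring a unique exact placement
#'
#' @param index A `unique_index` built on `genome`.
#' @param genome The [genome()].
#' @param seq Read sequence (length >= index seed length). `N` never matches.
#' @return A list with `status` (`"mapped"`, `"unmapped"` or `"multimapped"`);
#'   when mapped also `chrom`, `strand`, `start` (0-based forward coordinate
#'   of the covered interval) and `mapped_length`.
#' @export
map_read <- function(index, genome, seq) {
  seq <- toupper(seq)
  if (nchar(seq) < index$k) stop("read shorter than seed length")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN character")
  if (grepl("N", seq, fixed = TRUE))
    return(list(status = "unmapped"))
  fwd <- placements_fwd(index, genome, seq)
  rcs <- revcomp(seq)
  rev <- if (identical(rcs, seq)) fwd else placements_fwd(index, genome, rcs)
  n <- NROW(fwd) + NROW(rev)
  if (n == 0L) return(list(status = "unmapped"))
  if (n > 1L) return(list(status = "multimapped"))
  if (NROW(fwd) == 1L)
    list(status = "mapped", chrom = fwd$chrom, strand = "+",
         start = fwd$pos, mapped_length = nchar(seq))
  else
    list(status = "mapped", chrom = rev$chrom, strand = "-",
         start = rev$pos, mapped_length = nchar(seq))
}

#' Map a read with iterative 3' trimming
#'
#' Attempts the full read, then trims 4 bp from the 3' end and retries,
#' down to the seed length (76, 72, ..., 28 for a 76-mer). The first length
#' with a unique placement wins; multimapped attempts continue the cascade.
#'
#' @inheritParams map_read
#' @param trim_step Bases removed per attempt (default 4).
#' @return As [map_read()], plus `n_trims` and `attempted_lengths`.
#' @export
map_with_trimming <- function(index, genome, seq, trim_step = 4L) {
  seq <- toupper(seq)
  full <- nchar(seq)
  if (full < index$k) stop("read shorter than seed length")
  lens <- seq.int(full, index$k, by = -trim_step)
  for (len in lens) {
    res <- map_read(index, genome, substr(seq, 1L, len))
    if (res$status == "mapped") {
      res$n_trims <- (full - len) %/% trim_step
      res$attempted_lengths <- lens[lens >= len]
      return(res)
    }
  }
  list(status = "unmapped", attempted_lengths = lens)
}

#' Map a batch of reads
#'
#' @param index,genome As [map_read()].
#' @param reads Named character vector of read sequences.
#' @param trim Use the trimming cascade (default `TRUE`).
#' @return `data.frame` with one row per read: `read_id`, `status`, `chrom`,
#'   `strand`, `start`, `mapped_length`, `n_trims`.
#' @export
map_reads <- function(index, genome, reads, trim = TRUE) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  out <- data.frame(read_id = ids, status = "unmapped",
                    chrom = NA_character_, strand = NA_character_,
                    start = NA_integer_, mapped_length = NA_integer_,
                    n_trims = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    res <- if (trim) map_with_trimming(index, genome, reads[[i]])
           else map_read(index, genome, reads[[i]])
    out$status[i] <- res$status
    if (res$status == "mapped") {
      out$chrom[i] <- res$chrom
      out$strand[i] <- res$strand
      out$start[i] <- res$start
      out$mapped_length[i] <- res$mapped_length
      out$n_trims[i] <- if (is.null(res$n_trims)) 0L else res$n_trims
    }
  }
  out
}
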