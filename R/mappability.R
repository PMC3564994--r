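# Simulated-read mappability. For every base with room before the chromosome
# end, one 76-mer and one 28-mer are simulated per strand; each read that
# occurs exactly once in the genome (both strands counted) adds 1 to the
# track over its span on its own strand. An interior base of globally unique
# sequence is covered by 76 unique 76-mers and 28 unique 28-mers: score 104.
#
# Under exact matching, the occurrence count of a read's sequence equals that
# of its reverse complement's, so uniqueness of the plus- and minus-strand
# reads over the same interval coincides and one uniqueness vector per k-mer
# length serves both strands. Reads are counted at their own length, without
# the trimming cascade: only that reading yields the stated 104 maximum.

#' Compute the per-base mappability track
#'
#' @param genome A [genome()] object.
#' @param read_lengths Simulated read lengths (default `c(76, 28)`).
#' @return A `cov_track` (condition `"mappability"`); integer values in
#'   `[0, sum(read_lengths)]`, per strand.
#' @export
compute_mappability <- function(genome, read_lengths = c(76L, 28L)) {
  track <- empty_track(genome, "mappability")
  for (k in read_lengths) {
    # gather all forward k-mers genome-wide to count occurrences globally
    km_all <- character(0); ch_all <- character(0); pos_all <- integer(0)
    for (ch in names(genome)) {
      L <- chrom_len(genome, ch)
      if (L < k) next
      starts <- 0:(L - k)
      km <- substring(genome[[ch]], starts + 1L, starts + k)
      km_all <- c(km_all, km)
      ch_all <- c(ch_all, rep(ch, length(km)))
      pos_all <- c(pos_all, starts)
    }
    if (length(km_all) == 0L) next
    uk <- unique(km_all)
    cnt <- tabulate(match(km_all, uk), nbins = length(uk))
    rc <- revcomp(km_all)
    total <- cnt[match(km_all, uk)]
    j <- match(rc, uk)
    total <- total + ifelse(is.na(j), 0L, cnt[j])
    uniq <- total == 1L & !grepl("N", km_all, fixed = TRUE)
    for (ch in names(genome)) {
      sel <- ch_all == ch & uniq
      if (!any(sel)) next
      L <- chrom_len(genome, ch)
      p <- pos_all[sel]  # 0-based unique read starts
      d <- numeric(L + 1L)
      d[p + 1L] <- d[p + 1L] + 1
      d[p + k + 1L] <- d[p + k + 1L] - 1
      covk <- cumsum(d)[seq_len(L)]
      track$cov[[ch]][["+"]] <- track$cov[[ch]][["+"]] + covk
      track$cov[[ch]][["-"]] <- track$cov[[ch]][["-"]] + covk
    }
  }
  track
}

#' Is a gene mappable?
#'
#' A gene is mappable when the mean mappability over its annotated ORF, on
#' its own strand, is at least `cutoff` — default 94, i.e. 90% of the
#' perfect score of 104.
#'
#' @param track Mappability `cov_track` from [compute_mappability()].
#' @param gene One row of a gene-model `data.frame`.
#' @param cutoff Minimum mean score (default 94).
#' @return `TRUE` or `FALSE`.
#' @export
gene_mappable <- function(track, gene, cutoff = 94) {
  v <- track_slice(track, gene$chrom, gene$strand, gene$start, gene$end)
  mean(v) >= cutoff
}
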