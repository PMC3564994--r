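#' Create an empty stranded coverage track
#'
#' A coverage track stores one numeric vector per chromosome per strand
#' (length = chromosome length) plus a condition label. Raw tracks hold
#' non-negative integers (read-cover counts); normalized tracks hold reals.
#'
#' @param genome A [genome()] object giving chromosome lengths.
#' @param condition Condition label attached to the track.
#' @return A `cov_track` object.
#' @export
empty_track <- function(genome, condition = "cond") {
  cov <- lapply(names(genome), function(ch) {
    n <- chrom_len(genome, ch)
    list("+" = numeric(n), "-" = numeric(n))
  })
  names(cov) <- names(genome)
  structure(list(condition = condition, cov = cov), class = "cov_track")
}

#' @export
print.cov_track <- function(x, ...) {
  tot <- sum(vapply(x$cov, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]), 0))
  cat("cov_track [", x$condition, "]: ", length(x$cov),
      " chromosome(s), total signal ", format(tot), "\n", sep = "")
  invisible(x)
}

#' Per-base track values over an interval
#'
#' @param track A `cov_track`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`.
#' @export
track_slice <- function(track, chrom, strand, start, end) {
  v <- track$cov[[chrom]][[strand]]
  if (start < 0L || end > length(v)) stop("interval beyond chromosome end")
  v[(start + 1L):end]
}

track_add <- function(track, chrom, strand, start, end, amount = 1) {
  v <- track$cov[[chrom]][[strand]]
  if (start < 0L || end > length(v)) stop("read interval outside chromosome")
  v[(start + 1L):end] <- v[(start + 1L):end] + amount
  track$cov[[chrom]][[strand]] <- v
  track
}

#' Total signal in a coverage track (both strands)
#'
#' @param track A `cov_track`.
#' @return Sum of all per-base values.
#' @export
track_total <- function(track) {
  sum(vapply(track$cov, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]), 0))
}
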