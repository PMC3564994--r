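# Differential-end caller. For each gene the reference and condition
# coverage over an analysis window (ORF +/- flank) are log2-transformed and
# median-normalized over the ORF, where the two conditions should agree.
# The per-base difference d = cond - ref is scanned with a 10-bp and an
# 80-bp centred sliding window; a base qualifies when BOTH window means
# exceed the threshold T = max(3.5 * n, 2.0 log2 units), where n is the
# standard deviation of d over the annotated ORF (the gene's own noise).
# The first run of >= 40 qualifying bases nearest the ORF boundary, passing
# expression / intron / mappability filters, is the called end.

#' Caller parameters
#'
#' @param noise_multiplier Threshold multiple of the per-gene noise `n`
#'   (default 3.5).
#' @param min_fold_log2 Absolute floor on the threshold, in log2 units
#'   (default 2.0, i.e. fourfold).
#' @param window_small,window_large Sliding-window sizes in bp (10 and 80).
#' @param min_end_length Minimum called-end length in bp (default 40).
#' @param flank_max How far beyond the ORF boundary to scan (default 1000).
#' @param inset_max How far into the ORF to scan, to catch truncations that
#'   lose the start/stop codon (default 300).
#' @param min_region_expression Minimum mean raw coverage of the higher
#'   condition over a called run (default 5).
#' @param pseudocount Added before log2 (default 1).
#' @param mappability_cutoff Minimum mean mappability over a called run
#'   (default 94).
#' @param both_windows Require both windows to pass (`TRUE`, the default)
#'   or either.
#' @return A `caller_params` list.
#' @export
caller_params <- function(noise_multiplier = 3.5, min_fold_log2 = 2.0,
                          window_small = 10L, window_large = 80L,
                          min_end_length = 40L, flank_max = 1000L,
                          inset_max = 300L, min_region_expression = 5,
                          pseudocount = 1, mappability_cutoff = 94,
                          both_windows = TRUE) {
  p <- list(noise_multiplier = noise_multiplier,
            min_fold_log2 = min_fold_log2,
            window_small = as.integer(window_small),
            window_large = as.integer(window_large),
            min_end_length = as.integer(min_end_length),
            flank_max = as.integer(flank_max),
            inset_max = as.integer(inset_max),
            min_region_expression = min_region_expression,
            pseudocount = pseudocount,
            mappability_cutoff = mappability_cutoff,
            both_windows = isTRUE(both_windows))
  stopifnot(p$noise_multiplier > 0, p$min_fold_log2 >= 0,
            p$window_small <= p$window_large, p$min_end_length >= 1L)
  structure(p, class = "caller_params")
}

# analysis window: ORF +/- flank, clipped to the chromosome and at the
# nearest same-strand neighbour's ORF boundary
analysis_window <- function(gene, genome, genes, params) {
  lo <- gene$start - params$flank_max
  hi <- gene$end + params$flank_max
  same <- genes[genes$chrom == gene$chrom & genes$strand == gene$strand &
                genes$gene_id != gene$gene_id, , drop = FALSE]
  left <- same$end[same$end <= gene$start]
  right <- same$start[same$start >= gene$end]
  if (length(left) > 0L) lo <- max(lo, max(left))
  if (length(right) > 0L) hi <- min(hi, min(right))
  c(max(0L, lo), min(chrom_len(genome, gene$chrom), hi))
}

#' Median-normalize a reference/condition pair over a gene's window
#'
#' Both tracks are log2(v + pseudocount)-transformed over the analysis
#' window on the gene's strand; the condition track is shifted so the two
#' ORF medians coincide (removing global expression-level differences).
#'
#' @param track_ref,track_cond Raw `cov_track`s.
#' @param gene One gene-model row.
#' @param window 0-based half-open analysis window (from
#'   `analysis_window()`; defaults to ORF +/- `flank_max` clipped to the
#'   chromosome).
#' @param params A [caller_params()].
#' @return List: `window`, `ref`, `cond` (log2 vectors over the window),
#'   `shift` (amount added to the condition track).
#' @export
normalize_pair <- function(track_ref, track_cond, gene, params = caller_params(),
                           window = NULL) {
  if (is.null(window)) {
    L <- length(track_ref$cov[[gene$chrom]][[gene$strand]])
    window <- c(max(0L, gene$start - params$flank_max),
                min(L, gene$end + params$flank_max))
  }
  if (window[2L] <= window[1L]) stop("empty analysis window")
  r <- log2(track_slice(track_ref, gene$chrom, gene$strand,
                        window[1L], window[2L]) + params$pseudocount)
  cd <- log2(track_slice(track_cond, gene$chrom, gene$strand,
                         window[1L], window[2L]) + params$pseudocount)
  orf_idx <- (gene$start - window[1L] + 1L):(gene$end - window[1L])
  shift <- stats::median(r[orf_idx]) - stats::median(cd[orf_idx])
  list(window = window, ref = r, cond = cd + shift, shift = shift)
}

#' Per-gene noise level
#'
#' `n` is the (population) standard deviation of the normalized per-base
#' log2 difference, condition minus reference, over the annotated ORF —
#' where the medians have been matched, so any spread is noise.
#'
#' @param norm Output of [normalize_pair()].
#' @param gene The gene-model row used for normalization.
#' @return List: `gene_id`, `n`.
#' @export
noise_level <- function(norm, gene) {
  orf_idx <- (gene$start - norm$window[1L] + 1L):(gene$end - norm$window[1L])
  if (length(orf_idx) < 2L) stop("ORF shorter than 2 bases")
  d <- (norm$cond - norm$ref)[orf_idx]
  n <- sqrt(mean((d - mean(d))^2))
  list(gene_id = gene$gene_id, n = n)
}

# centred running mean with truncated edges
running_mean <- function(x, w) {
  n <- length(x)
  l <- (w - 1L) %/% 2L
  r <- w - 1L - l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - l, 1L)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# maximal runs of a constant value in an integer vector, as a data.frame
sign_runs <- function(s) {
  r <- rle(s)
  e <- cumsum(r$lengths)
  data.frame(start = e - r$lengths + 1L, end = e, sign = r$values)
}

#' Call a differential end on one side of one gene
#'
#' @param gene One gene-model row.
#' @param side 5 or 3 (transcript side).
#' @param norm Output of [normalize_pair()].
#' @param noise Output of [noise_level()].
#' @param params A [caller_params()].
#' @param track_ref,track_cond Raw tracks (for the expression filter).
#' @param mappability Optional mappability `cov_track`.
#' @return One-row `data.frame` describing the call, or `NULL`.
#' @export
call_differential_end <- function(gene, side, norm, noise, params,
                                  track_ref, track_cond,
                                  mappability = NULL) {
  win <- norm$window
  d <- norm$cond - norm$ref
  thr <- max(params$noise_multiplier * noise$n, params$min_fold_log2)
  m_s <- running_mean(d, params$window_small)
  m_l <- running_mean(d, params$window_large)
  qual <- if (params$both_windows)
    (m_s > thr & m_l > thr) - (m_s < -thr & m_l < -thr)
  else
    (m_s > thr | m_l > thr) - (m_s < -thr | m_l < -thr)
  # scan region and ORF boundary for this side/strand
  plus5 <- (side == 5L) == (gene$strand == "+")  # region upstream in genome?
  if (plus5) {
    b <- gene$start
    rlo <- win[1L]
    rhi <- min(gene$start + params$inset_max, gene$end)
  } else {
    b <- gene$end
    rlo <- max(gene$end - params$inset_max, gene$start)
    rhi <- win[2L]
  }
  ridx <- (rlo - win[1L] + 1L):(rhi - win[1L])
  runs <- sign_runs(qual[ridx])
  runs <- runs[runs$sign != 0L &
               (runs$end - runs$start + 1L) >= params$min_end_length, ,
               drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  # genome coordinates of each run (0-based half-open)
  runs$gstart <- rlo + runs$start - 1L
  runs$gend <- rlo + runs$end
  dist <- ifelse(runs$gstart <= b & b <= runs$gend, 0L,
                 pmin(abs(runs$gstart - b), abs(runs$gend - b)))
  runs <- runs[order(dist), , drop = FALSE]
  for (k in seq_len(nrow(runs))) {
    rn <- runs[k, ]
    hi_track <- if (rn$sign > 0L) track_cond else track_ref
    expr <- mean(track_slice(hi_track, gene$chrom, gene$strand,
                             rn$gstart, rn$gend))
    if (expr < params$min_region_expression) next
    iv <- gene$introns[[1L]]
    if (!is.null(iv) && nrow(iv) > 0L &&
        any(iv[, 1L] <= rn$gstart & rn$gend <= iv[, 2L])) next
    if (!is.null(mappability)) {
      mp <- mean(track_slice(mappability, gene$chrom, gene$strand,
                             rn$gstart, rn$gend))
      if (mp < params$mappability_cutoff) next
    }
    direction <- if (rn$sign > 0L) "longer" else "shorter"
    start_codon <- if (gene$strand == "+") c(gene$start, gene$start + 3L)
                   else c(gene$end - 3L, gene$end)
    stop_codon <- if (gene$strand == "+") c(gene$end - 3L, gene$end)
                  else c(gene$start, gene$start + 3L)
    covers <- function(cd) rn$gstart <= cd[1L] && cd[2L] <= rn$gend
    didx <- (rn$gstart - win[1L] + 1L):(rn$gend - win[1L])
    return(data.frame(gene_id = gene$gene_id,
                      condition = track_cond$condition,
                      side = side, direction = direction, chrom = gene$chrom,
                      start = rn$gstart, end = rn$gend,
                      mean_log2_diff = mean(d[didx]), n = noise$n,
                      start_codon_lost = direction == "shorter" && covers(start_codon),
                      stop_codon_lost = direction == "shorter" && covers(stop_codon),
                      stringsAsFactors = FALSE))
  }
  NULL
}

#' Call differential ends for all genes
#'
#' At most one 5' and one 3' call per gene. Genes failing the mappability
#' test are skipped (and listed in the result).
#'
#' @param track_ref,track_cond Raw `cov_track`s for the reference and test
#'   condition.
#' @param genome A [genome()] object.
#' @param genes Gene-model `data.frame`.
#' @param params A [caller_params()].
#' @param mappability Optional mappability `cov_track` from
#'   [compute_mappability()].
#' @return List: `ends` (`data.frame` of calls), `summary` (counts by side
#'   x direction), `skipped` (unmappable gene ids).
#' @export
call_all_ends <- function(track_ref, track_cond, genome, genes,
                          params = caller_params(), mappability = NULL) {
  calls <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!is.null(mappability) &&
        !gene_mappable(mappability, g, params$mappability_cutoff)) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    win <- analysis_window(g, genome, genes, params)
    norm <- normalize_pair(track_ref, track_cond, g, params, win)
    nz <- noise_level(norm, g)
    for (side in c(5L, 3L)) {
      res <- call_differential_end(g, side, norm, nz, params,
                                   track_ref, track_cond, mappability)
      if (!is.null(res)) calls[[length(calls) + 1L]] <- res
    }
  }
  ends <- if (length(calls) > 0L) do.call(rbind, calls)
          else data.frame(gene_id = character(0), condition = character(0),
                          side = integer(0), direction = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), mean_log2_diff = numeric(0),
                          n = numeric(0), start_codon_lost = logical(0),
                          stop_codon_lost = logical(0),
                          stringsAsFactors = FALSE)
  summary <- table(side = factor(ends$side, levels = c(5L, 3L)),
                   direction = factor(ends$direction,
                                      levels = c("longer", "shorter")))
  list(ends = ends, summary = summary, skipped = skipped)
}
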