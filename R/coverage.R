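#' Accumulate per-base coverage from mapped reads
#'
#' Each base's value is the number of mapped reads whose interval covers it,
#' accumulated on the read's own strand (strand-specific protocol).
#'
#' @param mapped `data.frame` from [map_reads()] (only `status == "mapped"`
#'   rows are used).
#' @param genome A [genome()] object.
#' @param condition Condition label for the track.
#' @return A raw `cov_track`.
#' @export
accumulate_coverage <- function(mapped, genome, condition = "cond") {
  track <- empty_track(genome, condition)
  m <- mapped[mapped$status == "mapped", , drop = FALSE]
  if (nrow(m) == 0L) return(track)
  if (any(m$start < 0L)) stop("read interval outside chromosome")
  for (ch in unique(m$chrom)) {
    L <- chrom_len(genome, ch)
    for (sd in c("+", "-")) {
      sel <- m$chrom == ch & m$strand == sd
      if (!any(sel)) next
      s <- m$start[sel]; e <- s + m$mapped_length[sel]
      if (any(e > L)) stop("read interval outside chromosome")
      d <- numeric(L + 1L)
      for (i in seq_along(s)) {       # starts may repeat; accumulate
        d[s[i] + 1L] <- d[s[i] + 1L] + 1
        d[e[i] + 1L] <- d[e[i] + 1L] - 1
      }
      track$cov[[ch]][[sd]] <- track$cov[[ch]][[sd]] + cumsum(d)[seq_len(L)]
    }
  }
  track
}

#' Mean expression of a gene
#'
#' Arithmetic mean of same-strand coverage across the annotated ORF.
#' Intron bases are included in the span by default; set
#' `exclude_introns = TRUE` to drop them.
#'
#' @param track A `cov_track`.
#' @param gene One row of a gene-model `data.frame`.
#' @param exclude_introns Drop intron bases from the mean.
#' @return Mean coverage (a single number).
#' @export
gene_expression <- function(track, gene, exclude_introns = FALSE) {
  v <- track_slice(track, gene$chrom, gene$strand, gene$start, gene$end)
  if (exclude_introns) {
    iv <- gene$introns[[1L]]
    if (!is.null(iv) && nrow(iv) > 0L) {
      drop <- unlist(lapply(seq_len(nrow(iv)), function(k)
        (iv[k, 1L] - gene$start + 1L):(iv[k, 2L] - gene$start)))
      v <- v[-drop]
    }
  }
  mean(v)
}

#' Build a genes-by-conditions expression matrix
#'
#' @param tracks Named list of raw `cov_track`s, one per condition.
#' @param genes Gene-model `data.frame`.
#' @param exclude_introns Passed to [gene_expression()].
#' @return Numeric matrix, rownames = gene ids, colnames = condition labels.
#' @export
expression_matrix <- function(tracks, genes, exclude_introns = FALSE) {
  m <- vapply(tracks, function(tr)
    vapply(seq_len(nrow(genes)), function(i)
      gene_expression(tr, genes[i, ], exclude_introns), 0), numeric(nrow(genes)))
  m <- matrix(m, nrow = nrow(genes),
              dimnames = list(genes$gene_id,
                              if (is.null(names(tracks)))
                                paste0("cond", seq_along(tracks))
                              else names(tracks)))
  m
}

#' Flag expressed genes
#'
#' A gene is expressed in a condition when each ORF base is detected
#' `threshold` or more times on average (mean raw coverage >= threshold).
#'
#' @param mat Raw (un-normalized) expression matrix from
#'   [expression_matrix()].
#' @param threshold Mean-coverage threshold (default 5).
#' @return `data.frame` of per-condition logicals plus an
#'   `expressed_anywhere` column.
#' @export
expressed_genes <- function(mat, threshold = 5) {
  flags <- mat >= threshold
  out <- as.data.frame(flags)
  out$expressed_anywhere <- rowSums(flags) > 0L
  out
}

#' Quantile-normalize an expression matrix
#'
#' Classical quantile normalization: each column's rank r is replaced by the
#' across-column mean of the r-th order statistics; tied values receive the
#' mean over their rank range.
#'
#' @param mat Numeric matrix (genes x conditions, >= 2 columns).
#' @return Normalized matrix; every column shares one sorted value multiset.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) {
    warning("quantile normalization needs >= 2 conditions; returning input")
    return(mat)
  }
  means <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- means
    stats::ave(res, col, FUN = mean)  # ties: mean over the rank range
  })
  dimnames(out) <- dimnames(mat)
  out
}
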