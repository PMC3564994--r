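# Poly(A) end tags: reads that fail to map at full length because they end
# in a run of >= 3 adenines the genome does not encode. The trailing A-run
# is stripped; if the remaining anchor (>= 28 bp) places uniquely and the
# genomic continuation does not itself reproduce the A-run, the first
# post-alignment base marks the cleavage site.

#' Call a poly(A) end tag from an unmapped read
#'
#' The caller is expected to pass reads that failed unique placement at
#' full length (a trimming-rescued read has lost its 3' evidence and is not
#' a tag candidate).
#'
#' @param index A `unique_index`.
#' @param genome The [genome()].
#' @param read Read sequence (transcript orientation).
#' @param read_id Identifier carried into the output.
#' @param min_tail Minimum trailing-A run (default 3).
#' @param min_anchor Minimum anchor length after stripping (default 28).
#' @return One-row `data.frame` (`read_id`, `chrom`, `strand`,
#'   `cleavage_pos`, `n_tail_A`) or `NULL`.
#' @export
call_end_tag <- function(index, genome, read, read_id = "read",
                         min_tail = 3L, min_anchor = 28L) {
  read <- toupper(read)
  m <- regmatches(read, regexpr("A+$", read))
  k <- if (length(m) == 0L) 0L else nchar(m)
  if (k < min_tail) return(NULL)
  anchor <- substr(read, 1L, nchar(read) - k)
  if (nchar(anchor) < min_anchor) return(NULL)  # tail too long to anchor
  res <- map_read(index, genome, anchor)
  if (res$status != "mapped") return(NULL)
  L <- chrom_len(genome, res$chrom)
  if (res$strand == "+") {
    cleav <- res$start + res$mapped_length
    dn <- genome_seq(genome, res$chrom, cleav, min(cleav + k, L))
    genomic <- nchar(dn) == k && dn == strrep("A", k)
  } else {
    cleav <- res$start - 1L
    lo <- max(res$start - k, 0L)
    dn <- genome_seq(genome, res$chrom, lo, res$start)
    genomic <- nchar(dn) == k && dn == strrep("T", k)
  }
  if (genomic) return(NULL)  # A-run is encoded: the read should map normally
  data.frame(read_id = read_id, chrom = res$chrom, strand = res$strand,
             cleavage_pos = cleav, n_tail_A = k, stringsAsFactors = FALSE)
}

#' Call end tags for a batch of reads
#'
#' Reads are first mapped at full length; only reads without a unique
#' full-length placement become tag candidates.
#'
#' @param index,genome As [call_end_tag()].
#' @param reads Named character vector of read sequences.
#' @param ... Passed to [call_end_tag()].
#' @return `data.frame` of tags (possibly zero rows).
#' @export
call_end_tags <- function(index, genome, reads, ...) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  out <- list()
  for (i in seq_along(reads)) {
    full <- map_read(index, genome, reads[[i]])
    if (full$status == "mapped") next
    tg <- call_end_tag(index, genome, reads[[i]], ids[i], ...)
    if (!is.null(tg)) out[[length(out) + 1L]] <- tg
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), cleavage_pos = integer(0),
                      n_tail_A = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cluster end tags into poly-adenylation sites
#'
#' Single-linkage: tags on the same chromosome and strand within
#' `cluster_window` bp of each other join one site. The representative
#' position is the mode of member cleavage positions (ties: smallest).
#'
#' @param tags Tag `data.frame` from [call_end_tags()].
#' @param cluster_window Linkage distance in bp (default 10).
#' @return `data.frame`: `chrom`, `strand`, `position` (representative),
#'   `tag_count`, plus a `members` list-column of member positions.
#' @export
cluster_tags <- function(tags, cluster_window = 10L) {
  out <- list()
  if (nrow(tags) > 0L) {
    for (key in unique(paste(tags$chrom, tags$strand))) {
      sel <- paste(tags$chrom, tags$strand) == key
      pos <- sort(tags$cleavage_pos[sel])
      brk <- c(0L, which(diff(pos) > cluster_window), length(pos))
      for (j in seq_len(length(brk) - 1L)) {
        mem <- pos[(brk[j] + 1L):brk[j + 1L]]
        tb <- table(mem)
        repr <- as.integer(names(tb)[which.max(tb)])
        out[[length(out) + 1L]] <- data.frame(
          chrom = tags$chrom[sel][1L], strand = tags$strand[sel][1L],
          position = repr, tag_count = length(mem),
          stringsAsFactors = FALSE)
        out[[length(out)]]$members <- list(mem)
      }
    }
  }
  if (length(out) == 0L) {
    z <- data.frame(chrom = character(0), strand = character(0),
                    position = integer(0), tag_count = integer(0),
                    stringsAsFactors = FALSE)
    z$members <- list()
    return(z)
  }
  do.call(rbind, out)
}

#' Report genes with multiple discrete poly-adenylation sites
#'
#' Sites are assigned to a gene when they lie on its strand inside the ORF
#' or within `assign_window` bp downstream of its 3' end. Among genes with
#' more than `min_tags` tags, a gene is multi-site when two site
#' representatives lie more than `min_separation` bp apart.
#'
#' @param sites `data.frame` from [cluster_tags()].
#' @param genes Gene-model `data.frame`.
#' @param min_tags Tag-count gate (strictly more than; default 10).
#' @param min_separation Minimum representative separation (default 50).
#' @param assign_window Downstream assignment window (default 300).
#' @return `data.frame` per gene passing the gate: `gene_id`, `n_tags`,
#'   `n_sites`, `multi_site`; attribute `fraction_multi`.
#' @export
multi_site_genes <- function(sites, genes, min_tags = 10L,
                             min_separation = 50L, assign_window = 300L) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$strand == "+") {
      sel <- sites$chrom == g$chrom & sites$strand == "+" &
        sites$position >= g$start & sites$position < g$end + assign_window
    } else {
      sel <- sites$chrom == g$chrom & sites$strand == "-" &
        sites$position >= g$start - assign_window & sites$position < g$end
    }
    if (!any(sel)) next
    ntags <- sum(sites$tag_count[sel])
    if (ntags <= min_tags) next
    pos <- sites$position[sel]
    multi <- length(pos) >= 2L && (max(pos) - min(pos)) > min_separation
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, n_tags = ntags, n_sites = sum(sel),
      multi_site = multi, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L)
    data.frame(gene_id = character(0), n_tags = integer(0),
               n_sites = integer(0), multi_site = logical(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  attr(out, "fraction_multi") <-
    if (nrow(out) > 0L) mean(out$multi_site) else NA_real_
  out
}
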