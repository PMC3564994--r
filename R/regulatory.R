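# Upstream ORFs and RBP motifs in differential 5'/3' ends, with
# sampling-based enrichment: observed totals are compared against totals
# over length-matched random segments (promoter windows for uORFs, the
# whole genome for motifs); z = (obs - mean) / sd, significant at z > 3.

STOP_CODONS <- c("TAA", "TAG", "TGA")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Find upstream ORFs whose start codon lies in a differential 5' end
#'
#' Scans the coding-strand sequence from the 5' edge of `end_interval`
#' through the main ORF. Every ATG inside `end_interval` and upstream of
#' the main start codon is extended to its first in-frame stop (searching
#' into the main ORF); ATGs without a stop before the ORF 3' boundary are
#' not reported.
#'
#' @param genome A [genome()] object.
#' @param gene One gene-model row.
#' @param end_interval 0-based half-open genome interval (the differential
#'   5' end), upstream of the main ATG on the coding strand.
#' @param strict Require the uORF stop to precede the main ATG
#'   (default `FALSE`: out-of-frame overlap with the main ORF is allowed).
#' @return `data.frame`: `gene_id`, `start_pos`, `stop_pos` (coding-strand
#'   genome coordinates of the first base of ATG / stop codon),
#'   `n_intervening_codons`, `minimal`, `frame` (0 = in frame with the main
#'   ORF), `overlaps_main_orf`.
#' @export
find_uorfs <- function(genome, gene, end_interval, strict = FALSE) {
  if (gene$strand == "+") {
    a <- end_interval[1L]
    if (a >= gene$start)
      stop("end_interval is not upstream of the main ORF")
    s <- genome_seq(genome, gene$chrom, a, gene$end, "+")
    t_main <- gene$start - a
    t_max <- end_interval[2L] - a
  } else {
    b <- end_interval[2L]
    if (b <= gene$end)
      stop("end_interval is not upstream of the main ORF")
    s <- genome_seq(genome, gene$chrom, gene$start, b, "-")
    t_main <- b - gene$end
    t_max <- b - end_interval[1L]
  }
  hits <- gregexpr("(?=ATG)", s, perl = TRUE)[[1L]]
  cand <- if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
  cand <- cand[cand < t_main & cand < t_max]
  rows <- list()
  slen <- nchar(s)
  for (t in cand) {
    j <- t + 3L
    stop_t <- NA_integer_
    while (j + 3L <= slen) {
      if (substr(s, j + 1L, j + 3L) %in% STOP_CODONS) { stop_t <- j; break }
      j <- j + 3L
    }
    if (is.na(stop_t)) next
    if (strict && stop_t >= t_main) next
    gp <- function(t0) if (gene$strand == "+") end_interval[1L] + t0
                       else end_interval[2L] - 1L - t0
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id,
      start_pos = gp(t), stop_pos = gp(stop_t),
      n_intervening_codons = (stop_t - t) %/% 3L - 1L,
      minimal = stop_t == t + 3L,
      frame = (t_main - t) %% 3L,
      overlaps_main_orf = stop_t >= t_main,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), start_pos = integer(0),
                      stop_pos = integer(0), n_intervening_codons = integer(0),
                      minimal = logical(0), frame = integer(0),
                      overlaps_main_orf = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# 0-based start positions where the IUPAC consensus matches (overlaps kept)
motif_positions <- function(sequence, consensus) {
  sc <- strsplit(sequence, "")[[1L]]
  if (any(!sc %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains letters outside {A,C,G,T,N}")
  m <- nchar(consensus)
  npos <- length(sc) - m + 1L
  if (npos < 1L) return(integer(0))
  cc <- strsplit(consensus, "")[[1L]]
  acc <- rep(TRUE, npos)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[cc[j]]]
    if (is.null(allowed)) stop("illegal IUPAC letter in consensus: ", cc[j])
    ok <- sc %in% allowed            # N in the sequence matches nothing
    acc <- acc & ok[j:(j + npos - 1L)]
  }
  which(acc) - 1L
}

#' Match an IUPAC-degenerate motif in a sequence
#'
#' Plain set-membership text search: a position matches when every
#' consensus letter's IUPAC set contains the sequence base (so AAACACAW
#' matches AAACACAA and AAACACAT). Overlapping matches are all reported;
#' no scoring. `N` in the sequence matches nothing.
#'
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @param consensus IUPAC consensus (U should already be normalized to T;
#'   see [read_motifs()]).
#' @param motif_id Identifier carried into the output.
#' @return `data.frame`: `motif_id`, `consensus`, `position` (0-based),
#'   `matched` substring.
#' @export
match_motifs <- function(sequence, consensus, motif_id = "motif") {
  sequence <- toupper(sequence)
  consensus <- gsub("U", "T", toupper(consensus), fixed = TRUE)
  pos <- motif_positions(sequence, consensus)
  data.frame(motif_id = rep(motif_id, length(pos)),
             consensus = rep(consensus, length(pos)),
             position = pos,
             matched = if (length(pos) == 0L) character(0)
                       else substring(sequence, pos + 1L,
                                      pos + nchar(consensus)),
             stringsAsFactors = FALSE)
}

#' Sampling null for uORF counts in differential ends
#'
#' Per iteration, each observed end length is matched by a random segment
#' of the same length wholly inside a random gene's promoter window (the
#' 1000 bp upstream of its start codon, coding strand); uORFs are counted
#' with [find_uorfs()] semantics and totalled.
#'
#' @param genome A [genome()] object.
#' @param genes Gene-model `data.frame` (sampling frame).
#' @param end_lengths Lengths (bp) of the observed differential ends;
#'   each must be <= `promoter_window`.
#' @param n_iter Number of null iterations (default 1000).
#' @param seed RNG seed.
#' @param promoter_window Upstream window size (default 1000).
#' @return Numeric vector of `n_iter` null totals.
#' @export
sample_uorf_null <- function(genome, genes, end_lengths, n_iter = 1000L,
                             seed = 1L, promoter_window = 1000L) {
  if (any(end_lengths > promoter_window))
    stop("end length exceeds the promoter window")
  set.seed(seed)
  ok <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") g$start >= promoter_window
    else g$end + promoter_window <= chrom_len(genome, g$chrom)
  }, TRUE)
  if (!any(ok)) stop("no gene has a clear promoter window")
  frame <- which(ok)
  totals <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    tot <- 0L
    for (L in end_lengths) {
      i <- frame[sample.int(length(frame), 1L)]
      g <- genes[i, ]
      d <- sample.int(promoter_window - L + 1L, 1L) - 1L
      seg <- if (g$strand == "+") c(g$start - d - L, g$start - d)
             else c(g$end + d, g$end + d + L)
      tot <- tot + nrow(find_uorfs(genome, g, seg))
    }
    totals[it] <- tot
  }
  totals
}

#' Sampling null for motif-match counts in differential ends
#'
#' Per iteration, each observed end length is matched by a segment drawn
#' uniformly from the whole genome (either strand); matches of all motifs
#' are totalled.
#'
#' @param genome A [genome()] object.
#' @param end_lengths Lengths (bp) of the observed ends.
#' @param motifs Motif `data.frame` from [read_motifs()] (or with columns
#'   `motif_id`, `consensus`).
#' @param n_iter Number of null iterations (default 1000).
#' @param seed RNG seed.
#' @return Numeric vector of `n_iter` null totals.
#' @export
sample_motif_null <- function(genome, end_lengths, motifs, n_iter = 1000L,
                              seed = 1L) {
  set.seed(seed)
  lens <- vapply(names(genome), function(ch) chrom_len(genome, ch), 0L)
  totals <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    tot <- 0L
    for (L in end_lengths) {
      ch <- sample(names(genome), 1L, prob = lens)
      st <- sample.int(lens[[ch]] - L + 1L, 1L) - 1L
      sd <- sample(c("+", "-"), 1L)
      s <- genome_seq(genome, ch, st, st + L, sd)
      for (k in seq_len(nrow(motifs)))
        tot <- tot + length(motif_positions(s, motifs$consensus[k]))
    }
    totals[it] <- tot
  }
  totals
}

#' Enrichment z-score against a sampling null
#'
#' @param observed Observed total count.
#' @param null_totals Null totals from a sampler.
#' @param label Optional label (condition x feature x direction).
#' @return `data.frame`: `label`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `n_samples`, `significant` (z > 3).
#' @export
zscore <- function(observed, null_totals, label = "") {
  if (length(null_totals) < 100L)
    warning("fewer than 100 null samples; z-score unstable")
  mu <- mean(null_totals)
  sd <- stats::sd(null_totals)
  if (!is.finite(sd) || sd == 0) stop("null sd is zero: z undefined")
  z <- (observed - mu) / sd
  data.frame(label = label, observed = observed, null_mean = mu,
             null_sd = sd, z = z, n_samples = length(null_totals),
             significant = z > 3, stringsAsFactors = FALSE)
}
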