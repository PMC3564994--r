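# Independent brute-force oracles used to check the fast implementations.

# occurrences of `s` across both strands of the genome (overlapping counted)
oracle_count_occurrences <- function(genome, s) {
  n <- 0L
  for (ch in names(genome)) {
    for (q in unique(c(s, revcomp(s)))) {
      hits <- gregexpr(paste0("(?=", q, ")"), genome[[ch]], perl = TRUE)[[1L]]
      if (hits[1L] != -1L) n <- n + length(hits)
    }
  }
  n
}

# exhaustive mappability: for each simulated same-strand read covering a
# base, count it when its sequence occurs exactly once genome-wide
oracle_mappability <- function(genome, chrom, strand, read_lengths = c(76L, 28L)) {
  L <- nchar(genome[[chrom]])
  out <- numeric(L)
  count_fixed <- function(hay, needle) {  # overlapping occurrences
    n <- 0L; from <- 1L
    repeat {
      i <- regexpr(needle, substr(hay, from, nchar(hay)), fixed = TRUE)
      if (i == -1L) break
      n <- n + 1L; from <- from + i
    }
    n
  }
  for (k in read_lengths) {
    if (L < k) next
    starts <- 0:(L - k)
    reads <- substring(genome[[chrom]], starts + 1L, starts + k)
    if (strand == "-") reads <- revcomp(reads)
    rcs <- revcomp(reads)
    for (j in seq_along(starts)) {
      if (grepl("N", reads[j], fixed = TRUE)) next
      tot <- 0L
      for (ch in names(genome)) {
        qs <- unique(c(reads[j], rcs[j]))
        for (q in qs) tot <- tot + count_fixed(genome[[ch]], q)
      }
      if (tot == 1L) {
        p <- starts[j]
        out[(p + 1L):(p + k)] <- out[(p + 1L):(p + k)] + 1
      }
    }
  }
  out
}

# exhaustive exact-match unique placement at one read length
oracle_map <- function(genome, s) {
  n <- oracle_count_occurrences(genome, s)
  if (n == 0L) "unmapped" else if (n > 1L) "multimapped" else "mapped"
}

# brute-force uORF scan matching find_uorfs semantics
oracle_uorfs <- function(genome, gene, end_interval, strict = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  if (gene$strand == "+") {
    s <- substr(genome[[gene$chrom]], end_interval[1L] + 1L, gene$end)
    t_main <- gene$start - end_interval[1L]
    t_max <- end_interval[2L] - end_interval[1L]
    gp <- function(t) end_interval[1L] + t
  } else {
    s <- revcomp(substr(genome[[gene$chrom]], gene$start + 1L, end_interval[2L]))
    t_main <- end_interval[2L] - gene$end
    t_max <- end_interval[2L] - end_interval[1L]
    gp <- function(t) end_interval[2L] - 1L - t
  }
  res <- list()
  for (t in 0:(nchar(s) - 3L)) {
    if (t >= t_main || t >= t_max) next
    if (substr(s, t + 1L, t + 3L) != "ATG") next
    j <- t + 3L
    stop_t <- NA_integer_
    while (j + 3L <= nchar(s)) {
      if (substr(s, j + 1L, j + 3L) %in% stops) { stop_t <- j; break }
      j <- j + 3L
    }
    if (is.na(stop_t)) next
    if (strict && stop_t >= t_main) next
    res[[length(res) + 1L]] <- c(start_pos = gp(t), stop_pos = gp(stop_t))
  }
  if (length(res) == 0L)
    return(data.frame(start_pos = integer(0), stop_pos = integer(0)))
  as.data.frame(do.call(rbind, res))
}

# IUPAC motif positions via regex expansion (the matcher never sees this)
oracle_motif_positions <- function(sequence, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  cc <- strsplit(consensus, "")[[1L]]
  rx <- paste0("(?=", paste0("[", vapply(cc, function(l) sets[[l]], ""), "]",
                             collapse = ""), ")")
  hits <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

# small fixture: a genome with known unique and duplicated regions
fixture_genome <- function(len = 6000L, seed = 11L, duplicate = FALSE) {
  g <- generate_genome(1L, len, gc = 0.4, seed = seed)
  if (duplicate) {
    rs <- data.frame(src_chrom = "chrI", src_start = 0L, src_end = 500L,
                     dst_chrom = "chrI", dst_start = len - 500L)
    g <- generate_genome(1L, len, gc = 0.4, seed = seed, repeat_spec = rs)
  }
  g
}

# quick two-condition fixture with one planted end
fixture_sim <- function(n_genes = 6L, diff = NULL, seed = 5L,
                        base_depth = 50, lengths = 25000L, bg = 0.005) {
  g <- generate_genome(1L, lengths, seed = seed)
  pg <- plant_genes(g, n_genes, seed = seed)
  plan <- truth_plan(pg$genes, diff = diff)
  sim <- simulate_condition_pair(pg$genome, pg$genes, plan,
                                 noise_spec(base_depth = base_depth),
                                 seed = seed + 1L, background_frac = bg)
  list(genome = pg$genome, genes = pg$genes, sim = sim)
}
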