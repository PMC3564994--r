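# Synthetic study generator. It emulates the design of the real experiment:
# a multi-chromosome genome, well-separated genes with promoters, and a
# reference-vs-stress pair of strand-specific coverage landscapes in which a
# chosen subset of genes carries a longer or shorter 5'/3' transcript end of
# known interval and fold. Every planted feature is recorded in a truth
# object sufficient to score the callers.

#' Noise specification for simulated coverage
#'
#' @param family `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (ignored for Poisson).
#' @param base_depth Mean per-base coverage of an expressed transcript.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(family = c("poisson", "negative_binomial"),
                       dispersion = 0.2, base_depth = 50) {
  family <- match.arg(family)
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (base_depth <= 0) stop("base_depth must be > 0")
  structure(list(family = family, dispersion = dispersion,
                 base_depth = base_depth), class = "noise_spec")
}

# sample from the values of x (safe when length(x) == 1)
sample_from <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

draw_counts <- function(mu, spec) {
  if (spec$family == "poisson") stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion)
}

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC content; `repeat_spec` optionally copies
#' segments verbatim to plant exact repeats (for mappability tests).
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths (recycled to `n_chrom`); each >= 2000.
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed; identical seeds give identical genomes.
#' @param repeat_spec Optional `data.frame` with columns `src_chrom`,
#'   `src_start`, `src_end`, `dst_chrom`, `dst_start` (0-based half-open):
#'   each row copies the source segment over the destination.
#' @return A [genome()] object.
#' @export
generate_genome <- function(n_chrom = 2L, lengths = 50000L, gc = 0.38,
                            seed = 1L, repeat_spec = NULL) {
  lengths <- rep_len(lengths, n_chrom)
  if (any(lengths < 2000L)) stop("chromosome length < minimal gene footprint")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
  names(seqs) <- paste0("chr", as.roman(seq_len(n_chrom)))
  g <- genome(seqs)
  if (!is.null(repeat_spec)) {
    for (i in seq_len(nrow(repeat_spec))) {
      r <- repeat_spec[i, ]
      seg <- genome_seq(g, r$src_chrom, r$src_start, r$src_end)
      g <- genome_replace(g, r$dst_chrom, r$dst_start, "+", seg)
    }
  }
  g
}

# random sense-strand codons free of stops (and of internal ATG starts when
# no_atg is set, used for uORF cassette interiors)
random_codons <- function(n, no_atg = FALSE) {
  if (n == 0L) return(character(0))
  alph <- if (no_atg) c("A", "C", "G") else c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- paste(sample(alph, 3L, replace = TRUE), collapse = "")
      if (!cd %in% stops && !(no_atg && cd == "ATG")) break
    }
    out[i] <- cd
  }
  out
}

#' Plant non-overlapping genes into a genome
#'
#' ORF sequences are overwritten on the coding strand to begin with ATG,
#' end with a stop codon and contain no internal in-frame stop; strands
#' alternate; consecutive footprints keep at least `spacing_min` intergenic
#' bases so a 1000-bp promoter window never reaches a neighbour.
#'
#' @param genome A [genome()] object.
#' @param n_genes Number of genes to place.
#' @param orf_len_range ORF length range in bp (rounded to codons).
#' @param spacing_min Minimum intergenic gap (default 1200).
#' @param seed RNG seed.
#' @return List with the edited `genome` and the `genes` model table.
#' @export
plant_genes <- function(genome, n_genes, orf_len_range = c(600L, 1200L),
                        spacing_min = 1200L, seed = 1L) {
  set.seed(seed)
  ids <- character(0); chs <- character(0); sds <- character(0)
  sts <- integer(0); ens <- integer(0)
  placed <- 0L
  for (ch in names(genome)) {
    pos <- spacing_min
    L <- chrom_len(genome, ch)
    while (placed < n_genes) {
      len <- sample_from(seq(orf_len_range[1L], orf_len_range[2L], by = 3L))
      if (pos + len + spacing_min > L) break
      placed <- placed + 1L
      ids <- c(ids, sprintf("GENE%04d", placed))
      chs <- c(chs, ch)
      sds <- c(sds, if (placed %% 2L == 1L) "+" else "-")
      sts <- c(sts, pos)
      ens <- c(ens, pos + len)
      pos <- pos + len + spacing_min + sample(0:200, 1L)
    }
    if (placed >= n_genes) break
  }
  if (placed < n_genes) stop("genome too small for requested genes")
  for (i in seq_len(placed)) {
    len <- ens[i] - sts[i]
    orf <- paste0("ATG",
                  paste(random_codons(len / 3L - 2L), collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    genome <- genome_replace(genome, chs[i], sts[i], sds[i], orf)
  }
  list(genome = genome,
       genes = gene_model(ids, chs, sds, sts, ens))
}

#' Build a per-gene plan of UTR lengths and planted differential ends
#'
#' @param genes Gene-model `data.frame`.
#' @param utr5,utr3 Reference UTR lengths (bp), recycled per gene.
#' @param diff Optional `data.frame` with columns `gene_id`,
#'   `side` (5 or 3), `direction` (`"longer"`/`"shorter"`), `offset` (bp)
#'   and `fold`; genes not listed stay non-differential.
#' @return A plan `data.frame` consumed by [simulate_condition_pair()].
#' @export
truth_plan <- function(genes, utr5 = 120L, utr3 = 100L, diff = NULL) {
  plan <- data.frame(gene_id = genes$gene_id,
                     utr5 = rep_len(utr5, nrow(genes)),
                     utr3 = rep_len(utr3, nrow(genes)),
                     side = NA_integer_, direction = NA_character_,
                     offset = NA_integer_, fold = NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(diff)) {
    j <- match(diff$gene_id, plan$gene_id)
    if (anyNA(j)) stop("diff plan names unknown gene")
    if (any(diff$fold <= 1)) stop("planted folds must be > 1")
    if (any(diff$offset < 1L)) stop("planted differential interval empty")
    plan$side[j] <- diff$side
    plan$direction[j] <- diff$direction
    plan$offset[j] <- diff$offset
    plan$fold[j] <- diff$fold
  }
  plan
}

# genome-coordinate transcript span for given UTR lengths
gene_span <- function(gene, utr5, utr3) {
  if (gene$strand == "+") c(gene$start - utr5, gene$end + utr3)
  else c(gene$start - utr3, gene$end + utr5)
}

# Nudge a transcript 3' end inward so the cleavage site sits in clean
# context: the last transcribed base and the first post-cleavage base are
# both non-A (transcript orientation). An A at either position makes the
# planted position irrecoverable in principle for any tail-stripping
# caller (the genomic A merges with the poly(A) tail), so the generator
# avoids planting there.
adjust_cleavage <- function(span, strand, chromseq, max_walk = 25L) {
  if (strand == "+") {
    e <- span[2L]
    while (e > span[2L] - max_walk && e > span[1L] + 1L &&
           (substr(chromseq, e, e) == "A" ||
            substr(chromseq, e + 1L, e + 1L) == "A")) e <- e - 1L
    span[2L] <- e
  } else {
    s <- span[1L]
    while (s < span[1L] + max_walk && s < span[2L] - 1L &&
           (substr(chromseq, s + 1L, s + 1L) == "T" ||
            substr(chromseq, s, s) == "T")) s <- s + 1L
    span[1L] <- s
  }
  span
}

#' Simulate a reference/condition coverage pair with planted ends
#'
#' Expected coverage is `base_depth` over each condition's transcript span
#' on the coding strand, a uniform low background elsewhere, and inside a
#' planted differential region: `base_depth` in the gaining condition
#' against background (longer ends), or `base_depth / fold` residual in the
#' losing condition (shorter ends). Counts are drawn per the noise spec.
#'
#' @param genome A [genome()] object.
#' @param genes Gene-model `data.frame`.
#' @param plan Plan from [truth_plan()].
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @param background_frac Background expression outside transcripts, as a
#'   fraction of `base_depth` (default 0.005; set 0 for clean unit tests).
#' @return List `ref` (cov_track), `cond` (cov_track), `truth`
#'   (`planted_truth`).
#' @export
simulate_condition_pair <- function(genome, genes, plan,
                                    noise = noise_spec(), seed = 1L,
                                    background_frac = 0.005) {
  set.seed(seed)
  bd <- noise$base_depth
  bg <- background_frac * bd
  mk_mu <- function() {
    lapply(stats::setNames(names(genome), names(genome)), function(ch) {
      n <- chrom_len(genome, ch)
      list("+" = rep(bg, n), "-" = rep(bg, n))
    })
  }
  mu_ref <- mk_mu(); mu_cond <- mk_mu()
  truth_genes <- vector("list", nrow(genes))
  spans <- matrix(NA_integer_, nrow(genes), 2L)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- plan[plan$gene_id == g$gene_id, ]
    if (nrow(p) != 1L) stop("plan missing gene ", g$gene_id)
    ref_span <- gene_span(g, p$utr5, p$utr3)
    ref_span <- adjust_cleavage(ref_span, g$strand, genome[[g$chrom]])
    cond_span <- ref_span
    diff_rec <- NULL
    if (!is.na(p$side)) {
      d <- if (p$direction == "longer") p$offset else -p$offset
      # the genome-coordinate edge carrying this side: span[1] when side and
      # strand agree (5' on +, 3' on -), else span[2]; extending a transcript
      # always moves span[1] down or span[2] up
      if ((p$side == 5L) == (g$strand == "+")) {
        cond_span[1L] <- ref_span[1L] - d
      } else {
        cond_span[2L] <- ref_span[2L] + d
      }
      if (p$side == 3L)
        cond_span <- adjust_cleavage(cond_span, g$strand, genome[[g$chrom]])
      region <- if ((p$side == 5L) == (g$strand == "+"))
        sort(c(ref_span[1L], cond_span[1L]))
      else
        sort(c(ref_span[2L], cond_span[2L]))
      diff_rec <- list(side = p$side, direction = p$direction,
                       interval = region, fold = p$fold)
    }
    lo <- min(ref_span[1L], cond_span[1L])
    hi <- max(ref_span[2L], cond_span[2L])
    if (lo < 0L || hi > chrom_len(genome, g$chrom))
      stop("transcript span outside chromosome for ", g$gene_id)
    # neighbour check: extended span must not touch another gene's footprint
    same <- which(genes$chrom == g$chrom & seq_len(nrow(genes)) != i)
    if (any(genes$start[same] < hi & genes$end[same] > lo))
      stop("differential region crosses a neighboring gene: ", g$gene_id)
    sd <- g$strand
    idx_ref <- (ref_span[1L] + 1L):ref_span[2L]
    idx_cond <- (cond_span[1L] + 1L):cond_span[2L]
    mu_ref[[g$chrom]][[sd]][idx_ref] <- bd
    mu_cond[[g$chrom]][[sd]][idx_cond] <- bd
    if (!is.null(diff_rec) && diff_rec$direction == "shorter") {
      ridx <- (diff_rec$interval[1L] + 1L):diff_rec$interval[2L]
      mu_cond[[g$chrom]][[sd]][ridx] <- bd / p$fold
    }
    cleav <- if (sd == "+") cond_span[2L] else cond_span[1L] - 1L
    truth_genes[[i]] <- list(
      gene_id = g$gene_id, chrom = g$chrom, strand = sd,
      ref_span = ref_span, cond_span = cond_span,
      polya_site = cleav, diff = diff_rec)
    spans[i, ] <- c(lo, hi)
  }
  ref <- empty_track(genome, "ref"); cond <- empty_track(genome, "cond")
  for (ch in names(genome)) for (sd in c("+", "-")) {
    ref$cov[[ch]][[sd]] <- draw_counts(mu_ref[[ch]][[sd]], noise)
    cond$cov[[ch]][[sd]] <- draw_counts(mu_cond[[ch]][[sd]], noise)
  }
  truth <- structure(list(seed = seed, noise = unclass(noise),
                          background_frac = background_frac,
                          genes = stats::setNames(truth_genes, genes$gene_id)),
                     class = "planted_truth")
  list(ref = ref, cond = cond, truth = truth)
}

#' Plant upstream ORF cassettes into a 5' UTR region
#'
#' Writes non-overlapping `ATG ... TAA` cassettes (6-60 nt, in multiples of
#' 3) into the region on the gene's coding strand. Cassette interiors use
#' T-free codons, so no internal stop or start can arise, and the borders
#' are patched so no accidental ATG spans them.
#'
#' @param genome A [genome()] object.
#' @param gene One gene-model row (the cassettes go on its coding strand).
#' @param region 0-based half-open genome interval inside the gene's
#'   (extended) 5' UTR.
#' @param n_uorfs Number of cassettes.
#' @param seed RNG seed.
#' @param len_range Cassette length range in nt (will be rounded to codons).
#' @return List with the edited `genome` and a `uorfs` truth `data.frame`
#'   (`start_pos` = genome coordinate of the A of ATG on the coding strand,
#'   `length` in nt).
#' @export
plant_uorfs <- function(genome, gene, region, n_uorfs, seed = 1L,
                        len_range = c(6L, 60L)) {
  set.seed(seed)
  rlen <- region[2L] - region[1L]
  lens <- sample_from(seq(max(6L, len_range[1L]), len_range[2L], by = 3L),
                      n_uorfs, replace = TRUE)
  if (sum(lens) + n_uorfs > rlen) stop("region too small for cassettes")
  # choose non-overlapping offsets (transcript orientation within region)
  cass_len <- lens[order(lens, decreasing = TRUE)]
  cass_off <- integer(0)
  placed <- matrix(numeric(0), ncol = 2L)
  for (k in seq_len(n_uorfs)) {
    len <- cass_len[k]
    ok <- FALSE
    for (try in 1:500) {
      o <- sample.int(rlen - len + 1L, 1L) - 1L
      if (nrow(placed) == 0L ||
          !any(o < placed[, 2L] & placed[, 1L] < o + len)) { ok <- TRUE; break }
    }
    if (!ok) stop("region too small for cassettes")
    placed <- rbind(placed, c(o, o + len))
    cass_off <- c(cass_off, o)
  }
  starts <- integer(n_uorfs); glo <- integer(n_uorfs)
  for (k in seq_len(n_uorfs)) {
    len <- cass_len[k]
    cassette <- paste0("ATG",
                       paste(random_codons(len / 3L - 2L, no_atg = TRUE),
                             collapse = ""), "TAA")
    if (gene$strand == "+") {
      gpos <- region[1L] + cass_off[k]
      genome <- genome_replace(genome, gene$chrom, gpos, "+", cassette)
      # border patch: trailing ...TAA + "TG" would create an ATG
      after <- genome_seq(genome, gene$chrom, gpos + len,
                          min(gpos + len + 2L, chrom_len(genome, gene$chrom)))
      if (identical(after, "TG"))
        genome <- genome_replace(genome, gene$chrom, gpos + len, "+", "C")
      starts[k] <- gpos
      glo[k] <- gpos
    } else {
      # transcript orientation runs right-to-left on the forward strand
      gend <- region[2L] - cass_off[k]        # exclusive, transcript start side
      gpos <- gend - len
      genome <- genome_replace(genome, gene$chrom, gpos, "-", cassette)
      before <- genome_seq(genome, gene$chrom, max(gpos - 2L, 0L), gpos)
      if (identical(before, "CA"))  # revcomp("TG")
        genome <- genome_replace(genome, gene$chrom, gpos - 1L, "-", "C")
      starts[k] <- gend - 1L                  # coding-strand first base (A)
      glo[k] <- gpos
    }
  }
  uorfs <- data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                      strand = gene$strand, start_pos = starts,
                      interval_lo = glo, length = cass_len,
                      stringsAsFactors = FALSE)
  uorfs <- uorfs[order(uorfs$start_pos), ]
  rownames(uorfs) <- NULL
  list(genome = genome, uorfs = uorfs)
}

#' Simulate strand-specific reads, optionally poly(A)-tailed
#'
#' Reads are sampled uniformly from each gene's transcript span on the
#' coding strand. A fraction of each gene's reads is generated to end at
#' the transcript's cleavage site with `k >= 3` nongenomic A bases
#' replacing the post-cleavage sequence.
#'
#' @param genome A [genome()] object.
#' @param truth `planted_truth` from [simulate_condition_pair()].
#' @param which_span `"ref"` or `"cond"`: which condition's spans to read.
#' @param read_len Read length (default 76).
#' @param depth Mean per-base read coverage.
#' @param polya_site_fraction Fraction of reads that carry a poly(A) tail at
#'   the cleavage site.
#' @param tail_len_range Tail length range (min >= 3).
#' @param seed RNG seed.
#' @return List `reads` (named character vector) and `truth`
#'   (`data.frame`: read_id, gene_id, tailed, cleavage_pos, n_tail_A).
#' @export
simulate_reads <- function(genome, truth, which_span = "cond",
                           read_len = 76L, depth = 5,
                           polya_site_fraction = 0.05,
                           tail_len_range = c(3L, 10L), seed = 1L) {
  if (tail_len_range[1L] < 3L) stop("tail_len_range min must be >= 3")
  set.seed(seed)
  reads <- character(0)
  rec <- list()
  rid <- 0L
  for (tg in truth$genes) {
    span <- if (which_span == "cond") tg$cond_span else tg$ref_span
    slen <- span[2L] - span[1L]
    if (read_len > slen) stop("read_len > transcript length for ", tg$gene_id)
    tx <- genome_seq(genome, tg$chrom, span[1L], span[2L], tg$strand)
    n <- max(1L, round(depth * slen / read_len))
    n_tail <- stats::rbinom(1L, n, polya_site_fraction)
    n_body <- n - n_tail
    if (n_body > 0L) {
      st <- sample.int(slen - read_len + 1L, n_body, replace = TRUE) - 1L
      for (s in st) {
        rid <- rid + 1L
        reads <- c(reads, substr(tx, s + 1L, s + read_len))
        rec[[rid]] <- list(read_id = sprintf("r%06d", rid),
                           gene_id = tg$gene_id, tailed = FALSE,
                           cleavage_pos = NA_integer_, n_tail_A = NA_integer_)
      }
    }
    if (n_tail > 0L) {
      ks <- sample_from(seq(tail_len_range[1L], tail_len_range[2L]), n_tail,
                        replace = TRUE)
      for (k in ks) {
        rid <- rid + 1L
        body <- substr(tx, slen - (read_len - k) + 1L, slen)
        reads <- c(reads, paste0(body, paste(rep("A", k), collapse = "")))
        rec[[rid]] <- list(read_id = sprintf("r%06d", rid),
                           gene_id = tg$gene_id, tailed = TRUE,
                           cleavage_pos = tg$polya_site, n_tail_A = k)
      }
    }
  }
  names(reads) <- vapply(rec, `[[`, "", "read_id")
  truth_df <- do.call(rbind, lapply(rec, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  list(reads = reads, truth = truth_df)
}

#' Write / read planted truth as JSON
#'
#' @param truth A `planted_truth` object.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  for (g in names(x$genes)) {
    x$genes[[g]]$ref_span <- unlist(x$genes[[g]]$ref_span)
    x$genes[[g]]$cond_span <- unlist(x$genes[[g]]$cond_span)
    if (!is.null(x$genes[[g]]$diff))
      x$genes[[g]]$diff$interval <- unlist(x$genes[[g]]$diff$interval)
  }
  structure(x, class = "planted_truth")
}
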