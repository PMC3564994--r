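# End-to-end orchestration: simulate (or load) -> mappability -> end calls
# -> uORF scan -> optional reads/tags -> score against planted truth.
# Identical config + seed gives identical outputs.

#' Build a pipeline run configuration
#'
#' @param label_ref,label_cond Condition labels; must differ.
#' @param seed Master RNG seed (stage seeds are derived from it).
#' @param n_genes,genome_lengths,n_chrom,gc,orf_len_range,spacing_min
#'   Synthetic-genome parameters (see [generate_genome()], [plant_genes()]).
#' @param utr5,utr3 Reference UTR lengths for the plan.
#' @param diff Differential-end plan `data.frame` (see [truth_plan()]).
#' @param noise A [noise_spec()].
#' @param params A [caller_params()].
#' @param background_frac Background coverage fraction.
#' @param with_reads Also simulate reads and recover poly(A) tags.
#' @param outdir Optional directory for artifacts (tracks, calls, truth,
#'   manifest).
#' @return A validated `run_config` list.
#' @export
run_config <- function(label_ref = "ypd", label_cond = "stress", seed = 1L,
                       n_genes = 20L, genome_lengths = 60000L, n_chrom = 2L,
                       gc = 0.38, orf_len_range = c(600L, 1200L),
                       spacing_min = 1200L, utr5 = 120L, utr3 = 100L,
                       diff = NULL, noise = noise_spec(),
                       params = caller_params(), background_frac = 0.005,
                       with_reads = FALSE, outdir = NULL) {
  if (identical(label_ref, label_cond))
    stop("reference condition must be distinct from the test condition")
  structure(list(label_ref = label_ref, label_cond = label_cond,
                 seed = as.integer(seed), n_genes = n_genes,
                 genome_lengths = genome_lengths, n_chrom = n_chrom, gc = gc,
                 orf_len_range = orf_len_range, spacing_min = spacing_min,
                 utr5 = utr5, utr3 = utr3, diff = diff, noise = noise,
                 params = params, background_frac = background_frac,
                 with_reads = with_reads, outdir = outdir),
            class = "run_config")
}

# small stable content hash for manifests (polynomial hash of the JSON
# encoding; doubles stay exact below 2^53)
config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(unclass(config), unclass), auto_unbox = TRUE,
                        null = "null", force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Stages: genome + gene planting, condition-pair simulation, mappability,
#' differential-end calling, uORF scan over differential 5' ends, optional
#' read simulation and poly(A)-tag recovery, scoring against the planted
#' truth. Artifacts are written when `config$outdir` is set.
#'
#' @param config A [run_config()].
#' @return List: `genome`, `genes`, `tracks`, `truth`, `mappability`,
#'   `ends`, `uorfs`, `tags`, `sites`, `score`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  g <- generate_genome(config$n_chrom, config$genome_lengths, config$gc,
                       seed = seed)
  pg <- plant_genes(g, config$n_genes, config$orf_len_range,
                    config$spacing_min, seed = seed + 1L)
  g <- pg$genome; genes <- pg$genes
  plan <- truth_plan(genes, config$utr5, config$utr3, config$diff)
  sim <- simulate_condition_pair(g, genes, plan, config$noise,
                                 seed = seed + 2L,
                                 background_frac = config$background_frac)
  sim$ref$condition <- config$label_ref
  sim$cond$condition <- config$label_cond
  mp <- compute_mappability(g)
  calls <- call_all_ends(sim$ref, sim$cond, g, genes, config$params, mp)
  # uORFs within called differential 5' ends (longer side only has UTR seq)
  uorfs <- list()
  e5 <- calls$ends[calls$ends$side == 5L, , drop = FALSE]
  for (k in seq_len(nrow(e5))) {
    gn <- genes[genes$gene_id == e5$gene_id[k], ]
    iv <- c(e5$start[k], e5$end[k])
    # clip to the upstream side of the main ATG
    if (gn$strand == "+") iv[2L] <- min(iv[2L], gn$start)
    else iv[1L] <- max(iv[1L], gn$end)
    if (iv[2L] - iv[1L] < 3L) next
    u <- find_uorfs(g, gn, iv)
    if (nrow(u) > 0L) { u$end_id <- k; uorfs[[length(uorfs) + 1L]] <- u }
  }
  uorfs <- if (length(uorfs) > 0L) do.call(rbind, uorfs) else NULL
  tags <- NULL; sites <- NULL; read_truth <- NULL
  if (isTRUE(config$with_reads)) {
    rd <- simulate_reads(g, sim$truth, which_span = "cond",
                         seed = seed + 3L)
    idx <- build_index(g)
    tags <- call_end_tags(idx, g, rd$reads)
    sites <- cluster_tags(tags)
    read_truth <- rd$truth
  }
  score <- score_against_truth(calls$ends, sim$truth,
                               tags = tags, tag_truth = read_truth)
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package_version = as.character(utils::packageVersion("endscan")),
                   n_genes = nrow(genes),
                   n_calls = nrow(calls$ends),
                   skipped_unmappable = length(calls$skipped))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    write_fasta(g, file.path(od, "genome.fa"))
    write_gff(genes, file.path(od, "genes.gff3"))
    for (sd in c("+", "-")) {
      tag <- if (sd == "+") "plus" else "minus"
      write_bedgraph(sim$ref, file.path(od, paste0(config$label_ref, "_", tag,
                                                   ".bedgraph")), sd)
      write_bedgraph(sim$cond, file.path(od, paste0(config$label_cond, "_", tag,
                                                    ".bedgraph")), sd)
    }
    write_truth(sim$truth, file.path(od, "truth.json"))
    utils::write.table(calls$ends, file.path(od, "ends.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(genome = g, genes = genes, tracks = list(ref = sim$ref, cond = sim$cond),
       truth = sim$truth, mappability = mp, ends = calls$ends,
       summary = calls$summary, skipped = calls$skipped, uorfs = uorfs,
       tags = tags, sites = sites, score = score, manifest = manifest)
}

interval_overlap <- function(a, b) max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]))

#' Score caller output against planted truth
#'
#' An end call matches a planted end when gene, side and direction agree
#' and the call covers at least half of the planted interval. Tags match
#' on exact cleavage position; uORFs on exact start position. With zero
#' calls, precision is reported as 1 with a `zero_calls` flag.
#'
#' @param ends End-call `data.frame` from [call_all_ends()].
#' @param truth `planted_truth` from [simulate_condition_pair()].
#' @param uorfs,uorf_truth Optional uORF calls and planted-uORF table
#'   (matched on `start_pos`).
#' @param tags,tag_truth Optional tag calls and read-truth table.
#' @return List of per-stage statistics (precision, recall, boundary
#'   errors, counts).
#' @export
score_against_truth <- function(ends, truth, uorfs = NULL, uorf_truth = NULL,
                                tags = NULL, tag_truth = NULL) {
  planted <- Filter(function(tg) !is.null(tg$diff), truth$genes)
  matched_truth <- logical(length(planted))
  names(matched_truth) <- vapply(planted, `[[`, "", "gene_id")
  matched_call <- logical(nrow(ends))
  berr <- numeric(0)
  for (i in seq_len(nrow(ends))) {
    e <- ends[i, ]
    tg <- truth$genes[[e$gene_id]]
    if (is.null(tg) || is.null(tg$diff)) next
    d <- tg$diff
    if (d$side != e$side || d$direction != e$direction) next
    ov <- interval_overlap(c(e$start, e$end), d$interval)
    if (ov / (d$interval[2L] - d$interval[1L]) >= 0.5) {
      matched_call[i] <- TRUE
      matched_truth[e$gene_id] <- TRUE
      berr <- c(berr, abs(e$start - d$interval[1L]),
                abs(e$end - d$interval[2L]))
    }
  }
  out <- list(ends = list(
    n_calls = nrow(ends), n_planted = length(planted),
    precision = if (nrow(ends) == 0L) 1 else mean(matched_call),
    zero_calls = nrow(ends) == 0L,
    recall = if (length(planted) == 0L) NA_real_ else mean(matched_truth),
    boundary_error_mean = if (length(berr) > 0L) mean(berr) else NA_real_,
    boundary_error_max = if (length(berr) > 0L) max(berr) else NA_real_))
  if (!is.null(tags) && !is.null(tag_truth)) {
    tt <- tag_truth[tag_truth$tailed, , drop = FALSE]
    hit <- tags$cleavage_pos[match(tt$read_id, tags$read_id)]
    out$tags <- list(
      n_tags = nrow(tags), n_planted = nrow(tt),
      recall = if (nrow(tt) == 0L) NA_real_
               else mean(!is.na(hit) & hit == tt$cleavage_pos),
      precision = if (nrow(tags) == 0L) 1
                  else mean(tags$read_id %in% tt$read_id &
                            tags$cleavage_pos ==
                              tt$cleavage_pos[match(tags$read_id, tt$read_id)],
                            na.rm = TRUE))
  }
  if (!is.null(uorfs) && !is.null(uorf_truth)) {
    out$uorfs <- list(
      n_calls = nrow(uorfs), n_planted = nrow(uorf_truth),
      recall = if (nrow(uorf_truth) == 0L) NA_real_
               else mean(uorf_truth$start_pos %in% uorfs$start_pos),
      precision = if (nrow(uorfs) == 0L) 1
                  else mean(uorfs$start_pos %in% uorf_truth$start_pos))
  }
  out
}
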