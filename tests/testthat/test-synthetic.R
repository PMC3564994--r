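test_that("genome generation is deterministic and honors GC and repeats", {
  g1 <- generate_genome(2L, 5000L, gc = 0.5, seed = 3L)
  g2 <- generate_genome(2L, 5000L, gc = 0.5, seed = 3L)
  expect_identical(unclass(g1), unclass(g2))
  expect_false(identical(unclass(g1),
                         unclass(generate_genome(2L, 5000L, gc = 0.5, seed = 4L))))
  # observed GC within 3 sd of binomial expectation at gc = 0.5
  big <- generate_genome(1L, 100000L, gc = 0.5, seed = 6L)
  n_gc <- sum(strsplit(big[["chrI"]], "")[[1L]] %in% c("G", "C"))
  expect_lt(abs(n_gc - 50000), 3 * sqrt(100000 * 0.25))
  # planted repeat: the two substrings are equal
  rs <- data.frame(src_chrom = "chrI", src_start = 0L, src_end = 500L,
                   dst_chrom = "chrII", dst_start = 0L)
  gr <- generate_genome(2L, 5000L, seed = 3L, repeat_spec = rs)
  expect_equal(substr(gr[["chrI"]], 1, 500), substr(gr[["chrII"]], 1, 500))
  expect_error(generate_genome(1L, 1000L), "minimal gene footprint")
})

test_that("planted genes are well-formed ORFs with clear spacing", {
  g <- generate_genome(2L, 30000L, seed = 6L)
  pg <- plant_genes(g, 12L, spacing_min = 1200L, seed = 6L)
  genes <- pg$genes
  expect_equal(nrow(genes), 12L)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(genes))) {
    orf <- genome_seq(pg$genome, genes$chrom[i], genes$start[i],
                      genes$end[i], genes$strand[i])
    expect_equal(nchar(orf) %% 3L, 0L)
    expect_equal(substr(orf, 1L, 3L), "ATG")
    expect_true(substr(orf, nchar(orf) - 2L, nchar(orf)) %in% stops)
    # no internal in-frame stop
    codons <- substring(orf, seq(1L, nchar(orf) - 3L, 3L),
                        seq(3L, nchar(orf) - 1L, 3L))
    expect_false(any(codons[-length(codons)] %in% stops))
  }
  # footprints (ORF +/- spacing) never overlap on a chromosome
  for (ch in unique(genes$chrom)) {
    gg <- genes[genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1L)
      expect_true(all(gg$start[-1L] - gg$end[-nrow(gg)] >= 1200L))
  }
  expect_error(plant_genes(g, 500L, seed = 1L), "too small")
})

test_that("condition-pair simulation matches its stated expectations", {
  fx <- fixture_sim(n_genes = 4L, base_depth = 50, bg = 0)
  tg <- fx$sim$truth$genes[[1L]]
  # no differential ends: same expectation, so ORF means agree within noise
  v_ref <- track_slice(fx$sim$ref, tg$chrom, tg$strand,
                       tg$ref_span[1L], tg$ref_span[2L])
  v_cond <- track_slice(fx$sim$cond, tg$chrom, tg$strand,
                        tg$cond_span[1L], tg$cond_span[2L])
  n <- length(v_ref)
  expect_lt(abs(mean(v_ref) - 50), 3 * sqrt(50 / n))   # CLT bound
  expect_lt(abs(mean(v_cond) - 50), 3 * sqrt(50 / n))
  # planted longer 5' end: condition expectation base_depth, reference ~ 0
  genes <- fx$genes
  fx2 <- fixture_sim(n_genes = 4L,
                     diff = data.frame(gene_id = genes$gene_id[2L], side = 5L,
                                       direction = "longer", offset = 200L,
                                       fold = 16),
                     base_depth = 50, bg = 0)
  d <- fx2$sim$truth$genes[[genes$gene_id[2L]]]$diff
  expect_equal(d$interval[2L] - d$interval[1L], 200L)
  r_in <- track_slice(fx2$sim$ref, genes$chrom[2L], genes$strand[2L],
                      d$interval[1L], d$interval[2L])
  c_in <- track_slice(fx2$sim$cond, genes$chrom[2L], genes$strand[2L],
                      d$interval[1L], d$interval[2L])
  expect_equal(sum(r_in), 0)
  expect_lt(abs(mean(c_in) - 50), 3 * sqrt(50 / 200))
  # determinism: identical seeds give identical tracks
  fx3 <- fixture_sim(n_genes = 4L, base_depth = 50, bg = 0)
  expect_identical(fx$sim$ref$cov, fx3$sim$ref$cov)
  expect_identical(fx$sim$cond$cov, fx3$sim$cond$cov)
})

test_that("shorter-end simulation leaves a residual of depth/fold", {
  fx <- fixture_sim(n_genes = 4L, seed = 13L)
  gid <- fx$genes$gene_id[3L]
  fx2 <- fixture_sim(n_genes = 4L, seed = 13L,
                     diff = data.frame(gene_id = gid, side = 3L,
                                       direction = "shorter", offset = 80L,
                                       fold = 20),
                     base_depth = 50, bg = 0)
  d <- fx2$sim$truth$genes[[gid]]$diff
  g3 <- fx2$genes[3L, ]
  c_in <- track_slice(fx2$sim$cond, g3$chrom, g3$strand,
                      d$interval[1L], d$interval[2L])
  r_in <- track_slice(fx2$sim$ref, g3$chrom, g3$strand,
                      d$interval[1L], d$interval[2L])
  expect_lt(abs(mean(r_in) - 50), 3 * sqrt(50 / 80))
  expect_lt(mean(c_in), 10)   # residual 50/20 = 2.5 per base
  expect_gt(mean(c_in), 0)
})

test_that("planted uORF cassettes are found by the scanner and do not overlap", {
  fx <- fixture_sim(n_genes = 4L, seed = 17L)
  for (i in c(1L, 2L)) {   # one + and one - strand gene
    g <- fx$genes[i, ]
    region <- if (g$strand == "+") c(g$start - 400L, g$start - 50L)
              else c(g$end + 50L, g$end + 400L)
    pu <- plant_uorfs(fx$genome, g, region, n_uorfs = 3L, seed = 31L)
    expect_equal(nrow(pu$uorfs), 3L)
    found <- find_uorfs(pu$genome, g, region)
    expect_true(all(pu$uorfs$start_pos %in% found$start_pos),
                info = paste("strand", g$strand))
    # cassettes do not overlap (forward-coordinate intervals)
    iv <- cbind(pu$uorfs$interval_lo, pu$uorfs$interval_lo + pu$uorfs$length)
    iv <- iv[order(iv[, 1L]), ]
    expect_true(all(iv[-1L, 1L] >= iv[-nrow(iv), 2L]))
  }
})

test_that("a minimal ATGTAA cassette yields exactly one minimal uORF there", {
  fx <- fixture_sim(n_genes = 2L, seed = 19L)
  g <- fx$genes[1L, ]
  region <- c(g$start - 60L, g$start - 40L)
  pu <- plant_uorfs(fx$genome, g, region, n_uorfs = 1L, seed = 7L,
                    len_range = c(6L, 6L))
  found <- find_uorfs(pu$genome, g, region)
  planted <- found[found$start_pos == pu$uorfs$start_pos, ]
  expect_equal(nrow(planted), 1L)
  expect_true(planted$minimal)
  expect_equal(planted$n_intervening_codons, 0L)
})

test_that("simulated reads are genome substrings; tails are nongenomic A-runs", {
  fx <- fixture_sim(n_genes = 3L, seed = 23L, bg = 0)
  rd <- simulate_reads(fx$genome, fx$sim$truth, depth = 3,
                       polya_site_fraction = 0.2, seed = 29L)
  tr <- rd$truth
  idx <- build_index(fx$genome)
  body <- rd$reads[!tr$tailed][1:10]
  for (s in body) {
    r <- map_read(idx, fx$genome, s)
    expect_equal(r$status, "mapped")
  }
  tails <- which(tr$tailed)[1:5]
  for (i in tails) {
    s <- rd$reads[[i]]
    k <- tr$n_tail_A[i]
    expect_equal(substr(s, nchar(s) - k + 1L, nchar(s)), strrep("A", k))
    # the tail differs from the genome continuation at the cleavage site
    tg <- fx$sim$truth$genes[[tr$gene_id[i]]]
    cont <- if (tg$strand == "+")
      genome_seq(fx$genome, tg$chrom, tr$cleavage_pos[i],
                 tr$cleavage_pos[i] + k)
    else
      genome_seq(fx$genome, tg$chrom, tr$cleavage_pos[i] - k + 1L,
                 tr$cleavage_pos[i] + 1L, "-")
    expect_false(identical(cont, strrep("A", k)))
  }
  # read yield ~ depth * transcribed / read_len (binomial-ish bound)
  spans <- vapply(fx$sim$truth$genes, function(tg)
    tg$cond_span[2L] - tg$cond_span[1L], 0)
  expected <- sum(round(3 * spans / 76))
  expect_lt(abs(length(rd$reads) - expected), 3 * sqrt(expected) + 3)
})

test_that("truth JSON round trips", {
  fx <- fixture_sim(n_genes = 3L,
                    diff = data.frame(gene_id = "GENE0002", side = 5L,
                                      direction = "longer", offset = 150L,
                                      fold = 8))
  f <- tempfile(fileext = ".json")
  write_truth(fx$sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$genes$GENE0002$diff$interval,
               fx$sim$truth$genes$GENE0002$diff$interval)
  expect_equal(back$genes$GENE0001$ref_span,
               fx$sim$truth$genes$GENE0001$ref_span)
  expect_equal(back$seed, fx$sim$truth$seed)
})
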