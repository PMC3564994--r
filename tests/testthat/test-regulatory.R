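test_that("minimal and ordinary uORFs are reported with correct fields", {
  # hand-built 5' UTR: ...ATGTAA... and ATG GCA GCA TAG upstream of main ATG
  utr <- paste0(strrep("C", 20L), "ATGTAA", strrep("C", 10L),
                "ATGGCAGCATAG", strrep("C", 12L))
  orf <- paste0("ATG", strrep("GCA", 20L), "TAA")
  g <- genome(c(chrI = paste0(strrep("G", 10L), utr, orf, strrep("G", 10L))))
  gstart <- 10L + nchar(utr)
  gene <- gene_model("g1", "chrI", "+", gstart, gstart + nchar(orf))[1, ]
  iv <- c(10L, gstart)
  u <- find_uorfs(g, gene, iv)
  expect_equal(nrow(u), 2L)
  m <- u[u$minimal, ]
  expect_equal(m$start_pos, 30L)
  expect_equal(m$stop_pos, 33L)
  expect_equal(m$n_intervening_codons, 0L)
  o <- u[!u$minimal, ]
  expect_equal(o$start_pos, 46L)
  expect_equal(o$n_intervening_codons, 2L)
  expect_false(any(u$overlaps_main_orf))
  # region with no ATG: empty
  expect_equal(nrow(find_uorfs(g, gene, c(10L, 28L))), 0L)
  # interval downstream of the start codon is rejected
  expect_error(find_uorfs(g, gene, c(gstart + 10L, gstart + 40L)),
               "not upstream")
})

test_that("uORF scanner matches the exhaustive oracle on random sequences", {
  set.seed(61)
  for (rep in 1:120) {
    L <- 2000L
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    g <- genome(c(chrI = s))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      gene <- gene_model("g", "chrI", "+", 1200L, 1800L)[1, ]
      iv_lo <- sample(100:800, 1L)
      iv <- c(iv_lo, iv_lo + sample(50:300, 1L))
    } else {
      gene <- gene_model("g", "chrI", "-", 200L, 800L)[1, ]
      iv_hi <- sample(1200:1900, 1L)
      iv <- c(iv_hi - sample(50:300, 1L), iv_hi)
    }
    strict <- rep %% 3L == 0L
    got <- find_uorfs(g, gene, iv, strict = strict)
    want <- oracle_uorfs(g, gene, iv, strict = strict)
    expect_equal(got$start_pos, want$start_pos,
                 info = sprintf("rep %d strand %s", rep, strand))
    expect_equal(got$stop_pos, want$stop_pos,
                 info = sprintf("rep %d strand %s", rep, strand))
  }
})

test_that("IUPAC motif matching reproduces the degenerate-consensus semantics", {
  expect_equal(nrow(match_motifs("AAACACAA", "AAACACAW")), 1L)
  expect_equal(nrow(match_motifs("AAACACAT", "AAACACAW")), 1L)
  expect_equal(nrow(match_motifs("AAACACAG", "AAACACAW")), 0L)
  # U in a consensus is treated as T
  expect_equal(nrow(match_motifs("AAACACAT", "AAACACAU")), 1L)
  # overlapping matches are all reported
  m <- match_motifs("AAAA", "AA")
  expect_equal(m$position, c(0L, 1L, 2L))
  # N in the sequence matches nothing
  expect_equal(nrow(match_motifs("AANA", "AA")), 1L)
})

test_that("motif matcher agrees with the regex-expansion oracle", {
  set.seed(62)
  letters_iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N")
  for (rep in 1:400) {
    s <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE),
               collapse = "")
    cons <- paste(sample(letters_iupac, sample(4:10, 1L), replace = TRUE),
                  collapse = "")
    got <- match_motifs(s, cons)$position
    want <- oracle_motif_positions(s, cons)
    expect_equal(got, want, info = cons)
  }
})

test_that("replacing a consensus letter by N never loses matches", {
  set.seed(63)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
               collapse = "")
    cons <- paste(sample(c("A", "C", "G", "T", "W", "S"), 6L, replace = TRUE),
                  collapse = "")
    n0 <- nrow(match_motifs(s, cons))
    j <- sample(6L, 1L)
    relaxed <- cons
    substr(relaxed, j, j) <- "N"
    expect_gte(nrow(match_motifs(s, relaxed)), n0)
  }
})

test_that("null samplers are deterministic and respect engineered genomes", {
  fx <- fixture_sim(n_genes = 4L, seed = 65L)
  lens <- c(120L, 200L)
  n1 <- sample_uorf_null(fx$genome, fx$genes, lens, n_iter = 30L, seed = 9L)
  n2 <- sample_uorf_null(fx$genome, fx$genes, lens, n_iter = 30L, seed = 9L)
  expect_identical(n1, n2)
  expect_length(n1, 30L)
  # empty end set: all totals zero
  expect_true(all(sample_uorf_null(fx$genome, fx$genes, integer(0),
                                   n_iter = 10L, seed = 1L) == 0))
  # ATG-free promoters: null mean 0 (C/G-only genome upstream of genes)
  g0 <- genome(c(chrI = strrep("CG", 3000L)))
  genes0 <- gene_model("g", "chrI", "+", 2000L, 3000L)
  expect_true(all(sample_uorf_null(g0, genes0, c(150L), n_iter = 20L,
                                   seed = 2L) == 0))
  # motif "N" matches everywhere: every total = sum of end lengths
  motifs_n <- data.frame(motif_id = "n", consensus = "N")
  tn <- sample_motif_null(fx$genome, lens, motifs_n, n_iter = 10L, seed = 3L)
  expect_true(all(tn == sum(lens)))
  # impossible motif on an A/T-only genome
  gat <- genome(c(chrI = strrep("AT", 3000L)))
  m4 <- data.frame(motif_id = "c", consensus = "CCCC")
  expect_true(all(sample_motif_null(gat, lens, m4, n_iter = 10L,
                                    seed = 4L) == 0))
  expect_identical(sample_motif_null(fx$genome, lens, motifs_n, 10L, 5L),
                   sample_motif_null(fx$genome, lens, motifs_n, 10L, 5L))
})

test_that("z-scores reproduce the direct formula and flag z > 3", {
  # a null with the moments reported for the salt uORF comparison:
  # mean 107, sd 9.7 -> z for 148 observed is (148-107)/9.7 = 4.227
  null <- c(rep(107 - 9.7, 50), rep(107 + 9.7, 50))
  stopifnot(abs(mean(null) - 107) < 1e-9)
  z <- zscore(148, null)
  expect_equal(z$z, (148 - 107) / stats::sd(null), tolerance = 1e-12)
  expect_equal(z$z, 4.227, tolerance = 0.01)
  expect_true(z$significant)
  z0 <- zscore(mean(null), null)
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  expect_error(zscore(5, rep(3, 100)), "sd is zero")
})

test_that("planted uORF enrichment is detected against the sampling null", {
  # genome whose promoters carry a background uORF density; three ends are
  # seeded with extra cassettes (≈3x density) and tested at z > 3
  fx <- fixture_sim(n_genes = 8L, seed = 67L, lengths = 40000L)
  g <- fx$genome
  ends <- list()
  for (i in c(1L, 3L, 5L)) {
    gn <- fx$genes[i, ]
    region <- if (gn$strand == "+") c(gn$start - 420L, gn$start - 20L)
              else c(gn$end + 20L, gn$end + 420L)
    pu <- plant_uorfs(g, gn, region, n_uorfs = 12L, seed = 70L + i,
                      len_range = c(6L, 12L))
    g <- pu$genome
    ends[[length(ends) + 1L]] <- list(gene = gn, interval = region)
  }
  observed <- sum(vapply(ends, function(e)
    nrow(find_uorfs(g, e$gene, e$interval)), 0L))
  lens <- vapply(ends, function(e) e$interval[2L] - e$interval[1L], 0L)
  null <- sample_uorf_null(g, fx$genes, lens, n_iter = 300L, seed = 71L)
  z <- zscore(observed, null)
  expect_gt(z$z, 3)
})
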