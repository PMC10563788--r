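iv <- function(chromosome, start, end, score = NULL) {
  d <- data.frame(chromosome = chromosome, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(score)) d$score <- score
  d
}

win <- function(start, end, chromosome = "chr1", gene_id = "g") {
  data.frame(gene_id = gene_id, chromosome = chromosome, start = start,
             end = end, stringsAsFactors = FALSE)
}

uniform_map <- function(rate, len = 5e6, by = 10000, chromosome = "chr1") {
  pos <- seq(0, len, by = by)
  genetic_map(chromosome, pos, pos * rate / 1e6)
}

test_that("windows center on the gene midpoint with the requested size", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chromosome = "chr1",
                      start = c(100, 1000, 1001), end = c(200, 2000, 1999),
                      stringsAsFactors = FALSE)
  w <- gene_center_windows(genes, 100)
  expect_equal(w$start[1], 100)
  expect_equal(w$end[1], 200)
  expect_equal(w$end - w$start, rep(100, 3))
  # two genes sharing a center give identical (overlapping) windows
  expect_equal(w$start[2], w$start[3])

  # truncation at chromosome start and end, flagged
  genes2 <- data.frame(gene_id = c("lo", "hi"), chromosome = "chr1",
                       start = c(10, 990), end = c(30, 1000),
                       stringsAsFactors = FALSE)
  w2 <- gene_center_windows(genes2, 100, chrom_lengths = c(chr1 = 1000))
  expect_equal(w2$start[1], 0)
  expect_true(w2$truncated[1])
  expect_equal(w2$end[2], 1000)
  expect_true(w2$truncated[2])
  expect_error(gene_center_windows(genes2, 100, chrom_lengths = c(chrX = 1)),
               "chr1")
  expect_error(gene_center_windows(genes2, 99), "%%")
})

test_that("genetic positions interpolate linearly within the search limit", {
  m <- genetic_map("chr1", c(100000, 200000), c(0.1, 0.3))
  expect_equal(genetic_position(m, "chr1", 150000, 50000), 0.2)
  # exact map point: returned regardless of max_search
  expect_equal(genetic_position(m, "chr1", 200000, 1), 0.3)
  # flanking point too far on one side
  m2 <- genetic_map("chr1", c(99000, 210000), c(0.1, 0.3))
  expect_true(is.na(genetic_position(m2, "chr1", 150001, 50000)))
  # no extrapolation beyond the map
  expect_true(is.na(genetic_position(m, "chr1", 50, 1e9)))
  expect_true(is.na(genetic_position(m, "chr1", 5e6, 1e9)))
  # unknown chromosome
  expect_true(is.na(genetic_position(m, "chrZ", 150000, 50000)))
})

test_that("genetic position is monotone non-decreasing where defined", {
  set.seed(91)
  pos <- sort(sample(1:1e6, 40))
  cm <- cumsum(runif(40, 0, 0.05))
  m <- genetic_map("chr1", pos, cm)
  q <- sort(sample(1:1e6, 300))
  g <- genetic_position(m, "chr1", q, 1e6)
  g <- g[!is.na(g)]
  expect_true(all(diff(g) >= 0))
})

test_that("window recombination rate reduces to the map's closed forms", {
  # uniform maps: rate exactly c for every standard window size
  for (c_rate in c(0.5, 1.5, 3)) {
    m <- uniform_map(c_rate)
    for (size in c(50000, 1e5, 2e5, 5e5, 1e6)) {
      w <- win(2e6 - size / 2, 2e6 + size / 2)
      expect_identical(window_recombination_rate(m, w),
                       (genetic_position(m, "chr1", w$end, 50000) -
                          genetic_position(m, "chr1", w$start, 50000)) /
                         (size / 1e6))
      expect_equal(window_recombination_rate(m, w), c_rate,
                   tolerance = 1e-12)
    }
  }
  # hand case: edges at 0.1 and 0.3 cM, 100 kb window -> 2 cM/Mb
  m <- genetic_map("chr1", c(100000, 200000), c(0.1, 0.3))
  expect_equal(window_recombination_rate(m, win(100000, 200000)), 2.0)
  # flat map segment -> exactly 0
  m0 <- genetic_map("chr1", c(0, 1000, 201000), c(0.2, 0.2, 0.2))
  expect_equal(window_recombination_rate(m0, win(1000, 201000)), 0)
  # missing edge position propagates
  expect_true(is.na(window_recombination_rate(m, win(100000, 400000))))
})

test_that("interval densities merge, clip and exclude gaps", {
  w <- win(0, 200)
  # half coverage
  expect_equal(interval_density(iv("chr1", 0, 100), w), 0.5)
  # overlapping intervals are merged, not double counted
  expect_equal(interval_density(iv("chr1", c(0, 40), c(60, 100)), w), 0.5)
  # invariance to splitting into abutting pieces
  expect_equal(interval_density(iv("chr1", c(0, 30, 60), c(30, 60, 100)), w),
               0.5)
  # gap bases leave numerator and denominator
  gaps <- iv("chr1", 150, 200)
  expect_equal(interval_density(iv("chr1", 0, 75), w, gaps), 0.5)
  # interval inside a gap contributes nothing
  expect_equal(interval_density(iv("chr1", c(0, 160), c(75, 200)), w, gaps),
               0.5)
  # window entirely gap: undefined
  expect_true(is.na(interval_density(iv("chr1", 0, 100), win(300, 400),
                                     iv("chr1", 250, 450))))
  # no intervals on the chromosome: zero
  expect_equal(interval_density(iv("chr2", 0, 100), w), 0)
  expect_true(all(interval_density(iv("chr1", 0, 1e6), w) <= 1))
})

test_that("score thresholds keep coverage at or below the target fraction", {
  # three equal-length intervals, scores 1..3, budget one third
  tr <- iv("chr1", c(0, 200, 400), c(100, 300, 500), score = c(1, 2, 3))
  res <- suppressMessages(score_threshold_for_fraction(tr, 300, 1/3))
  expect_equal(res$threshold, 3)
  expect_equal(res$achieved_fraction, 1/3, tolerance = 1e-12)
  # target above the covered fraction keeps everything: minimum score
  res2 <- suppressMessages(score_threshold_for_fraction(tr, 400, 0.999))
  expect_equal(res2$threshold, 1)
  # degenerate tie: single score class too large -> empty selection
  tr3 <- iv("chr1", c(0, 200), c(100, 300), score = c(5, 5))
  expect_warning(
    res3 <- suppressMessages(score_threshold_for_fraction(tr3, 300, 1/3)),
    "empty")
  expect_gt(res3$threshold, 5)
  expect_equal(nrow(apply_score_threshold(tr3, res3$threshold)), 0L)
  expect_error(suppressMessages(
    score_threshold_for_fraction(tr[0, ], 300, 0.5)), "empty interval set")
})

test_that("random scored interval sets reproduce the accumulate oracle", {
  set.seed(97)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    starts <- cumsum(sample(50:500, n))       # gaps >= 50, widths < 50:
    tr <- iv("chr1", starts, starts + sample(10:45, n, replace = TRUE),
             score = sample(1:8, n, replace = TRUE))
    G <- max(tr$end) * 2
    target <- runif(1, 0.05, 0.6)
    got <- withCallingHandlers(
      suppressMessages(score_threshold_for_fraction(tr, G, target)),
      warning = function(w) invokeRestart("muffleWarning"))
    expect_equal(got$threshold, bf_threshold(tr, G, target))
    expect_lte(got$achieved_fraction, target)
    # raising the threshold above any tie class never increases coverage
    kept <- apply_score_threshold(tr, got$threshold)
    expect_lte(sum(kept$end - kept$start), target * G)
  }
})

test_that("GC content counts G+C over unambiguous bases only", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "GCGCATATGCNNNNAT"))
  expect_equal(gc_content(seqs, win(0, 4)), 1.0)
  expect_equal(gc_content(seqs, win(4, 8)), 0.0)
  # ATGCNN -> 2 GC / 4 unambiguous
  expect_equal(gc_content(seqs, win(6, 12)), 0.5)
  # all-N window undefined
  expect_true(is.na(gc_content(seqs, win(10, 14))))
  expect_error(gc_content(seqs, win(0, 4, chromosome = "chr9")), "chr9")
})

test_that("VIP distances use edge-to-edge gaps with overlap giving zero", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      chromosome = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1000, 5000, 4500, 100),
                      end = c(2000, 6000, 5500, 200),
                      stringsAsFactors = FALSE)
  is_vip <- c(FALSE, TRUE, FALSE, FALSE)
  d <- distance_to_nearest_vip(genes, is_vip)
  expect_equal(d[1], 3000)          # gap 5000 - 2000
  expect_equal(d[2], 0)             # itself a VIP
  expect_equal(d[3], 0)             # overlaps the VIP
  expect_true(is.na(d[4]))          # no VIP on chr2
  # center convention as the configurable alternative
  dc <- distance_to_nearest_vip(genes, is_vip, convention = "center")
  expect_equal(dc[1], (5000 + 6000) / 2 - (1000 + 2000) / 2)
})

test_that("gene counts include every >= 1 bp overlap exactly once", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chromosome = "chr1",
                      start = c(100, 250, 400), end = c(200, 300, 500),
                      stringsAsFactors = FALSE)
  expect_identical(gene_number(genes, win(0, 260)), 2L)
  expect_identical(gene_number(genes, win(199, 200)), 1L)
  expect_identical(gene_number(genes, win(200, 250)), 0L)
  expect_identical(gene_number(genes, win(0, 1000)), 3L)
})

test_that("local recombination around elements is the span-weighted rate", {
  # uniform map: mean equals the constant rate whatever the layout
  m <- uniform_map(2, len = 1e5, by = 1000)
  el <- iv("chr1", c(20000, 50000), c(21000, 52000))
  r <- local_recombination_around_elements(m, el, win(0, 1e5))
  expect_equal(r$local_recomb, 2, tolerance = 1e-12)
  expect_gt(r$local_recomb_n, 0)

  # two-segment map (1 then 3 cM/Mb) with flanks covering equal spans
  pos <- seq(0, 20000, by = 1000)
  cm <- cumsum(c(0, ifelse(pos[-1] <= 10000, 1, 3) * 0.001))
  m2 <- genetic_map("chr1", pos, cm)
  el2 <- iv("chr1", 9999, 10001)     # flank 5 kb each side of the boundary
  r2 <- local_recombination_around_elements(m2, el2, win(0, 20000),
                                            flank = 5000)
  expect_equal(r2$local_recomb, 2, tolerance = 1e-6)

  # no map points within the flanks: undefined with a zero count
  m3 <- genetic_map("chr1", c(0, 90000), c(0, 0.1))
  r3 <- local_recombination_around_elements(m3, el, win(10000, 80000))
  expect_true(is.na(r3$local_recomb))
  expect_identical(r3$local_recomb_n, 0L)

  # elements outside the window are ignored
  r4 <- local_recombination_around_elements(m, iv("chr1", 1, 2), win(5e4, 6e4))
  expect_true(is.na(r4$local_recomb))
})

test_that("gene-level covariates apply the documented transforms", {
  genes <- data.frame(gene_id = c("a", "b"), chromosome = "chr1",
                      start = c(100, 500), end = c(1100, 600),
                      stringsAsFactors = FALSE)
  scalars <- data.frame(gene_id = c("a", "b"), tpm_mean = c(0, 3),
                        tpm_testis = c(1, 7), tpm_immune = c(15, 0),
                        ppi_count = c(0, 7), is_vip = c(FALSE, TRUE))
  d <- derived_gene_covariates(genes, scalars)
  expect_equal(d$gene_length, c(1000, 100))
  expect_equal(d$log2_ppi, c(0, 3))            # log2(1), log2(8)
  expect_equal(d$expression_mean, log2(c(1, 4)))
  expect_equal(d$expression_testis, log2(c(2, 8)))
  expect_error(derived_gene_covariates(genes, scalars[1, ]), "no scalar data")
  scalars$tpm_mean[1] <- -1
  expect_error(derived_gene_covariates(genes, scalars), ">= 0")
})

test_that("the greedy non-overlap filter keeps a maximal left-to-right subset", {
  w <- data.frame(chromosome = "chr1", start = c(0, 50, 90, 200, 210),
                  end = c(100, 150, 190, 300, 310))
  keep <- select_non_overlapping(w)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # three mutually overlapping windows: exactly one survives
  w3 <- data.frame(chromosome = "chr1", start = c(0, 10, 20),
                   end = c(100, 110, 120))
  expect_identical(sum(select_non_overlapping(w3)), 1L)
})

test_that("readers validate dialects with positional diagnostics", {
  tmp <- tempfile()
  writeLines(c("chr1\t10\t20", "chr1\t30\t25"), tmp)
  expect_error(read_bed(tmp), "line 2")
  writeLines(c("chr1\t10\t20\tx\t3.5"), tmp)
  b <- read_bed(tmp)
  expect_equal(b$score, 3.5)
  expect_error(read_bed("/nonexistent.bed"), "not found")

  writeLines(c("chromosome\tposition\tcm", "chr1\t100\t0.2", "chr1\t200\t0.1"),
             tmp)
  expect_error(read_genetic_map(tmp), "decreases at line 3")
  writeLines(c("chromosome\tposition\tcm", "chr1\t100\t0.2", "chr1\t100\t0.2"),
             tmp)
  expect_error(read_genetic_map(tmp), "duplicated position")

  writeLines(c("chromosome\tstart\tend\tgene_id", "chr1\t10\t5\tg1"), tmp)
  expect_error(read_gene_table(tmp), "line 1")
  writeLines(c("chromosome\tstart\tend\tgene_id",
               "chr1\t10\t50\tg1", "chr1\t10\t50\tg1"), tmp)
  expect_error(read_gene_table(tmp), "duplicated gene_id")
})
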