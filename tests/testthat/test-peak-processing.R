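test_that("window counting matches direct enumeration and the naive oracle", {
  tt <- tag_table(data.frame(chrom = "chr1", pos = c(100, 200, 600)),
                  genome_size = 1e6)
  win <- data.frame(chrom = "chr1", start = 100, end = 201, center = 150)
  expect_equal(count_window_tags(tt, win, 250)$count, 2L)

  # empty window and full-cover bound
  far <- data.frame(chrom = "chr1", start = 5000, end = 5101)
  expect_equal(count_window_tags(tt, far, 250)$count, 0L)
  all_win <- data.frame(chrom = "chr1", start = 0, end = 1001, center = 300)
  expect_equal(count_window_tags(tt, all_win, 1e5)$count, 3L)

  # absent chromosome: zero count with a warning
  other <- data.frame(chrom = "chrX", start = 0, end = 100)
  expect_warning(res <- count_window_tags(tt, other, 250), "absent")
  expect_equal(res$count, 0L)

  # random fixture vs naive double loop
  set.seed(303)
  tags <- data.frame(chrom = sample(c("chr1", "chr2"), 5000, TRUE),
                     pos = sample.int(1e5, 5000, TRUE))
  tt2 <- tag_table(tags, genome_size = 1e5)
  wins <- rand_peaks(200, max_pos = 1e5)
  hw <- 250
  got <- count_window_tags(tt2, wins, hw)$count
  naive <- vapply(seq_len(nrow(wins)), function(i) {
    sum(tags$chrom == wins$chrom[i] &
          abs(tags$pos - wins$center[i]) <= hw)
  }, numeric(1))
  expect_equal(as.numeric(got), naive)
})

test_that("fold enrichment is the density ratio with FE = 1 at background", {
  expect_equal(fold_enrichment(100, 501, 1e7, 2.7e9), (100 / 501) / (1e7 / 2.7e9))
  expect_equal(round(fold_enrichment(100, 501, 1e7, 2.7e9), 2), 53.89)
  expect_equal(fold_enrichment(0, 501, 1e7, 2.7e9), 0)
  bg_count <- 1e7 * 501 / 2.7e9
  expect_equal(fold_enrichment(bg_count, 501, 1e7, 2.7e9), 1)
  # scale invariance: doubling count and library size leaves FE fixed
  expect_equal(fold_enrichment(200, 501, 2e7, 2.7e9),
               fold_enrichment(100, 501, 1e7, 2.7e9))
  expect_error(fold_enrichment(10, 501, 0, 2.7e9), "total_tags")
})

test_that("ChIP/ATAC filters apply strict thresholds and preserve order", {
  mk <- function(q, fe1, fe2) {
    data.frame(chrom = "chr1", start = seq_along(q) * 1000,
               end = seq_along(q) * 1000 + 200,
               q_value = q, fe_1 = fe1, fe_2 = fe2)
  }
  p <- mk(q = c(1e-5, 1e-5, 1e-3, 1e-4), fe1 = c(12, 12, 50, 50),
          fe2 = c(15, 9, 50, 50))
  kept <- suppressMessages(filter_chip_peaks(p))
  expect_equal(kept$start, 1000L)       # row 2 fails FE, 3 fails q, 4 q == max
  expect_error(filter_chip_peaks(mk(NA, 1, 1)), "q_value")

  strong <- mk(q = rep(1e-6, 3), fe1 = c(25, 25, 21), fe2 = c(21, 20, 20.01))
  ks <- suppressMessages(filter_strong_peaks(strong))
  expect_equal(ks$start, c(1000L, 3000L)) # FE exactly 20 is dropped
  expect_equal(nrow(suppressMessages(filter_strong_peaks(strong[0, ]))), 0)

  atac <- data.frame(chrom = "chr1", start = c(1, 2, 3) * 1000,
                     end = c(1, 2, 3) * 1000 + 200,
                     fe_1 = c(4, 4, 3.01), fe_2 = c(5, 5, 3.01),
                     fe_3 = c(6, 3, 3.01))
  ka <- suppressMessages(filter_atac_peaks(atac))
  expect_equal(ka$start, c(1000L, 3000L))
  expect_error(filter_atac_peaks(atac[, -6]), "expected 3")
})

test_that("filters are monotone in their thresholds", {
  set.seed(404)
  n <- 200
  p <- rand_peaks(n)
  p$q_value <- runif(n, 0, 1e-2)
  p$fe_1 <- runif(n, 0, 40)
  p$fe_2 <- runif(n, 0, 40)
  strict <- suppressMessages(filter_chip_peaks(p, q_max = 1e-4, fe_min = 15))
  relaxed <- suppressMessages(filter_chip_peaks(p, q_max = 1e-3, fe_min = 10))
  expect_true(all(strict$peak_id %in% relaxed$peak_id))
})

test_that("peak_replicate_fe attaches one FE column per replicate library", {
  set.seed(505)
  tags1 <- tag_table(data.frame(chrom = "chr1",
                                pos = sample.int(1e5, 2e4, TRUE)),
                     genome_size = 1e5)
  tags2 <- tag_table(data.frame(chrom = "chr1",
                                pos = sample.int(1e5, 1e4, TRUE)),
                     genome_size = 1e5)
  pk <- rand_peaks(20, chroms = "chr1", max_pos = 1e5)
  out <- peak_replicate_fe(pk, list(tags1, tags2))
  expect_true(all(c("fe_1", "fe_2") %in% names(out)))
  # uniform tags: FE should hover near the background expectation of 1
  expect_true(abs(mean(out$fe_1) - 1) < 0.5)
})
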