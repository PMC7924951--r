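test_that("center_distance handles identity, arithmetic and chromosome mismatch", {
  a <- data.frame(chrom = "chr1", start = 100, end = 300)
  expect_equal(center_distance(a, a), 0)
  b1 <- data.frame(chrom = "chr1", start = 0, end = 200)
  b2 <- data.frame(chrom = "chr1", start = 200, end = 400)
  expect_equal(center_distance(b1, b2), 200)
  expect_equal(center_distance(b2, b1), 200)
  c2 <- data.frame(chrom = "chr2", start = 0, end = 200)
  expect_identical(center_distance(b1, c2), Inf)
})

test_that("interval validation rejects malformed input and honours summits", {
  expect_error(as_peak_tbl(data.frame(chrom = "chr1", start = 10, end = 10)),
               "start must be < end")
  expect_error(as_peak_tbl(data.frame(chrom = "chr1", start = -5, end = 10)),
               ">= 0")
  expect_error(as_peak_tbl(data.frame(chrom = "chr1", start = 0, end = 10,
                                      center = 10)),
               "center")
  p <- as_peak_tbl(data.frame(chrom = "chr1", start = 100, end = 301))
  expect_equal(p$center, 200L)
  p2 <- as_peak_tbl(data.frame(chrom = "chr1", start = 100, end = 301,
                               center = 150))
  expect_equal(p2$center, 150L)
})

test_that("match_peak_sets applies the inclusive 150 bp rule", {
  a <- data.frame(chrom = "chr1", start = c(900, 4900), end = c(1100, 5100))
  b <- data.frame(chrom = "chr1", start = c(1000, 8900), end = c(1200, 9100))
  m <- match_peak_sets(a, b)
  expect_equal(nrow(m$matched), 1)
  expect_equal(m$matched$center_a, 1000L)
  expect_equal(m$matched$center_b, 1100L)
  expect_equal(m$unique_a$center, 5000L)
  expect_equal(m$unique_b$center, 9000L)

  # identity: everything matches
  mi <- match_peak_sets(a, a)
  expect_equal(nrow(mi$matched), 2)
  expect_equal(nrow(mi$unique_a), 0)

  # boundary: 150 matches, 151 does not
  x <- data.frame(chrom = "chr1", start = 0, end = 2, center = 0)
  y150 <- data.frame(chrom = "chr1", start = 0, end = 200, center = 150)
  y151 <- data.frame(chrom = "chr1", start = 0, end = 200, center = 151)
  expect_equal(nrow(match_peak_sets(x, y150)$matched), 1)
  expect_equal(nrow(match_peak_sets(x, y151)$matched), 0)

  expect_error(match_peak_sets(a, b, threshold = -1), "positive")
})

test_that("matching is symmetric and agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:120, 1)
    m <- sample(5:120, 1)
    a <- rand_peaks(n, max_pos = sample(c(2e4, 1e5, 1e6), 1))
    b <- rand_peaks(m, max_pos = sample(c(2e4, 1e5, 1e6), 1))
    thr <- sample(c(150, 500, 2000), 1)
    got <- match_peak_sets(a, b, thr)
    ora <- oracle_match_sets(a, b, thr)
    pairs <- dplyr::arrange(got$matched, idx_a)
    expect_equal(pairs$idx_a, ora$idx_a)
    expect_equal(pairs$idx_b, ora$idx_b)
    # label-swap symmetry of the pair set
    swap <- match_peak_sets(b, a, thr)$matched
    expect_setequal(paste(pairs$idx_a, pairs$idx_b),
                    paste(swap$idx_b, swap$idx_a))
    # matched within threshold; residual cross pairs all beyond it
    expect_true(all(pairs$distance <= thr))
    if (nrow(got$unique_a) > 0 && nrow(got$unique_b) > 0) {
      d <- center_dist_matrix(got$unique_a, got$unique_b)
      expect_true(all(d > thr))
    }
    # per-side tallies reconcile
    expect_equal(nrow(pairs) + nrow(got$unique_a), nrow(a))
    expect_equal(nrow(pairs) + nrow(got$unique_b), nrow(b))
  }
})

test_that("merge_peaks chains left-to-right with midpoint replacement", {
  p <- function(centers) tibble::tibble(chrom = "chr1", start = centers,
                                        end = centers + 2, center = centers)
  expect_equal(merge_peaks(p(c(1000, 1100, 5000)))$center, c(1050L, 5000L))
  expect_equal(merge_peaks(p(c(0, 140, 280)))$center, c(70L, 280L))
  single <- merge_peaks(p(42))
  expect_equal(single$center, 42L)
  expect_equal(nrow(merge_peaks(p(numeric(0)))), 0)
})

test_that("merge_peaks is idempotent and separates output centers", {
  set.seed(202)
  for (rep in 1:20) {
    pk <- rand_peaks(sample(10:150, 1), max_pos = sample(c(5e3, 5e4), 1))
    thr <- 150
    merged <- merge_peaks(pk, thr)
    # pairwise separation within chromosome
    for (ch in unique(merged$chrom)) {
      cc <- sort(merged$center[merged$chrom == ch])
      if (length(cc) > 1) expect_true(all(diff(cc) > thr))
    }
    # member tally preserved
    expect_equal(sum(merged$n_merged), nrow(pk))
    # idempotence
    again <- merge_peaks(merged, thr)
    expect_equal(again$center, merged$center)
    # oracle agreement per chromosome
    for (ch in unique(pk$chrom)) {
      expect_equal(as.numeric(sort(merged$center[merged$chrom == ch])),
                   oracle_merge_centers(pk$center[pk$chrom == ch], thr))
    }
  }
})
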