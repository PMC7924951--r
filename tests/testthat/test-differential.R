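mk_counts <- function(mat, samples = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(mat)))
  dimnames(mat) <- list(sprintf("g%03d", seq_len(nrow(mat))), samples)
  mat
}

test_that("size factors follow the median-of-ratios construction", {
  # identical samples
  m <- mk_counts(matrix(rep(c(5, 10, 20), 3), ncol = 3))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))
  # featurewise doubling forces factors proportional to (1, 2)
  m2 <- mk_counts(cbind(c(10, 20, 40), c(20, 40, 80)))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # single feature {4, 16}: geometric mean 8 -> (0.5, 2)
  expect_equal(unname(size_factors(mk_counts(matrix(c(4, 16), 1)))),
               c(0.5, 2))
  # no universally nonzero feature
  expect_error(size_factors(mk_counts(matrix(c(0, 5, 5, 0), 2))),
               "nonzero")
  expect_error(size_factors(mk_counts(matrix(c(-1, 5), 1))), "non-negative")
})

test_that("nb_wald_test returns the null identity and flips under label swap", {
  set.seed(808)
  base <- matrix(rnbinom(300 * 6, mu = 100, size = 10), 300, 6)
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("A", "B"), each = 3))
  # identical counts in both groups: LFC 0 and p 1 everywhere
  same <- mk_counts(cbind(base[, 1:3], base[, 1:3]))
  fit0 <- nb_wald_test(same, design)
  expect_true(all(tidy(fit0)$log2_fold_change == 0))
  expect_true(all(tidy(fit0)$p_value == 1))

  counts <- mk_counts(base)
  fab <- tidy(nb_wald_test(counts, design, "A", "B"))
  fba <- tidy(nb_wald_test(counts, design, "B", "A"))
  expect_lt(max(abs(fab$log2_fold_change + fba$log2_fold_change)), 1e-12)
  expect_lt(max(abs(fab$p_value - fba$p_value)), 1e-12)
  # BH never decreases a p-value
  expect_true(all(fab$p_adjusted >= fab$p_value))

  expect_error(nb_wald_test(counts, design[c(1, 4:6), ]), "at least 2")
})

test_that("NB test is calibrated under the null and powered for 8-fold effects", {
  null_sim <- simulate_counts(sim_config(seed = 21, preset = "de_null"))
  fit <- nb_wald_test(null_sim$counts, null_sim$design)
  type1 <- mean(tidy(fit)$p_value < 0.05)
  expect_gte(type1, 0.03)
  expect_lte(type1, 0.07)

  pow_sim <- simulate_counts(sim_config(seed = 22, preset = "de_power"))
  fitp <- tidy(nb_wald_test(pow_sim$counts, pow_sim$design))
  de <- pow_sim$truth$true_lfc != 0
  expect_gt(mean(fitp$p_adjusted[de] < 0.05), 0.8)
  # planted direction is recovered
  expect_true(all(fitp$log2_fold_change[de & fitp$p_adjusted < 0.05] > 0))
})

test_that("NB fold changes agree with DESeq2 on the same data", {
  sim <- simulate_counts(sim_config(seed = 23, preset = "de_power",
                                    n_genes = 400, n_de = 40))
  fit <- tidy(nb_wald_test(sim$counts, sim$design))
  mat <- as.matrix(sim$counts[, -1])
  rownames(mat) <- sim$counts$feature
  coldata <- data.frame(group = factor(sim$design$group,
                                       levels = c("low", "high")))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    mat, coldata, design = ~group))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("group", "high", "low"))
  expect_gt(cor(fit$log2_fold_change, res$log2FoldChange,
                use = "complete.obs"), 0.95)
  ours <- fit$feature[fit$p_adjusted < 0.05]
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.05]
  overlap <- length(intersect(ours, theirs)) /
    max(1, length(union(ours, theirs)))
  expect_gt(overlap, 0.7)
})

test_that("TPM normalises columns to one million and ignores depth", {
  counts <- mk_counts(matrix(c(10, 20), 2, 1))
  lens <- data.frame(feature = c("g001", "g002"), length = c(1000, 2000))
  tpm <- compute_tpm(counts, lens)
  expect_equal(tpm$s1, c(5e5, 5e5))
  # single feature is forced to 1e6
  expect_equal(compute_tpm(mk_counts(matrix(7, 1, 1)),
                           c(g001 = 500))$s1, 1e6)
  # depth invariance
  tpm2 <- compute_tpm(mk_counts(matrix(c(20, 40), 2, 1)), lens)
  expect_equal(tpm$s1, tpm2$s1)
  sim <- simulate_counts(sim_config(seed = 24, n_genes = 500))
  tt <- compute_tpm(sim$counts, sim$lengths)
  sums <- colSums(tt[, -1])
  expect_true(all(abs(sums - 1e6) / 1e6 < 1e-6))
  expect_error(compute_tpm(counts, c(g001 = 1000)), "cover every feature")
})

test_that("differential-gene calling applies the strict TPM/FC/p rules", {
  diff <- tibble::tibble(
    feature = paste0("g", 1:4),
    log2_fold_change = c(log2(25), 1, log2(3), 2),
    p_value = c(0.001, 1e-6, 0.001, 0.05),
    p_adjusted = c(0.01, 1e-5, 0.01, 0.1)
  )
  tpm <- tibble::tibble(
    feature = paste0("g", 1:4),
    s1 = c(50, 4, 29.5, 50), s2 = c(50, 4, 29.5, 50),
    s3 = c(2, 2, 9.5, 2), s4 = c(2, 2, 9.5, 2)
  )
  design <- tibble::tibble(sample = paste0("s", 1:4),
                           group = rep(c("B", "A"), each = 2))
  called <- call_differential_genes(diff, tpm, design,
                                    group_a = "A", group_b = "B")
  # g1: passes everything; g2 fails TPM and FC; g3 FC exactly 3 (strict);
  # g4 p exactly 0.05 (strict)
  expect_equal(called$feature, "g1")
  expect_equal(called$direction, "up_in_b")
  expect_error(call_differential_genes(diff, tpm[-1, ], design,
                                       group_a = "A", group_b = "B"),
               "missing TPM")
})

test_that("DAR calling recovers a planted accessibility shift", {
  set.seed(909)
  n_win <- 300
  mu <- matrix(200, n_win, 6)
  mu[1:10, 4:6] <- 2000 # ten 10-fold more accessible windows in group B
  counts <- mk_counts(matrix(rnbinom(n_win * 6, mu = mu, size = 20),
                             n_win, 6))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("low", "high"), each = 3))
  dars <- suppressMessages(call_dars(counts, design, "low", "high"))
  expect_true(all(sprintf("g%03d", 1:10) %in% dars$feature))
  expect_true(all(dars$higher_in[dars$feature %in%
                                   sprintf("g%03d", 1:10)] == "high"))
  # false discoveries among the null windows stay near the BH target
  expect_lt(sum(!dars$feature %in% sprintf("g%03d", 1:10)), 10)

  # windows identical across conditions are never DARs
  same <- mk_counts(cbind(mu[, 1:3] * 0 + 100, mu[, 1:3] * 0 + 100))
  d2 <- suppressMessages(call_dars(same, design, "low", "high"))
  expect_equal(nrow(d2), 0)

  # window construction around merged peaks
  merged <- merge_peaks(data.frame(chrom = "chr1",
                                   start = c(1000, 1050, 9000),
                                   end = c(1400, 1450, 9400)))
  win <- dar_windows(merged, 500)
  expect_equal(win$start, merged$center - 500L)
  expect_equal(win$end, merged$center + 501L)
})
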