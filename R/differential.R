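#' @keywords internal
#' Coerce count input (matrix with rownames, or tibble whose first
#' column holds feature ids) to a named integer matrix.
count_input <- function(counts) {
  if (is.data.frame(counts)) {
    feats <- as.character(counts[[1]])
    mat <- as.matrix(counts[, -1, drop = FALSE])
    rownames(mat) <- feats
  } else {
    mat <- as.matrix(counts)
    if (is.null(rownames(mat))) {
      rownames(mat) <- sprintf("feature_%05d", seq_len(nrow(mat)))
    }
  }
  storage.mode(mat) <- "double"
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  mat
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of its count to the feature's geometric mean over samples, using
#' only features with nonzero counts in every sample. This is the
#' standard library-composition-robust normalisation for count data.
#'
#' @param counts Count matrix (features x samples) or a tibble whose
#'   first column holds feature ids.
#' @return Named numeric vector of positive per-sample scaling factors.
#' @examples
#' size_factors(matrix(c(4, 16), 1, 2,
#'              dimnames = list("g1", c("s1", "s2")))) # 0.5, 2
#' @export
size_factors <- function(counts) {
  mat <- count_input(counts)
  ok <- rowSums(mat > 0) == ncol(mat)
  if (!any(ok)) {
    stop("no feature has nonzero counts in every sample; ",
         "consider a pseudo-reference on filtered features", call. = FALSE)
  }
  log_geo <- rowMeans(log(mat[ok, , drop = FALSE]))
  sf <- apply(mat[ok, , drop = FALSE], 2,
              function(col) exp(median(log(col) - log_geo)))
  sf
}

#' Negative-binomial Wald test between two groups
#'
#' A documented, self-contained two-group differential test for count
#' data. Counts are normalised by median-of-ratios [size_factors()];
#' per-feature group means on the normalised scale give the fold change
#' `log2((mu_B + 0.5) / (mu_A + 0.5))`; the NB dispersion `alpha` in the
#' variance model `Var = mu + alpha * mu^2` is estimated by method of
#' moments from the within-group residuals and, by default, smoothed
#' across features through a fitted mean-dispersion trend
#' `alpha(mu) = a + b / mu` (floored at 1e-8). With only a handful of
#' replicates a raw per-feature moment estimate is too noisy for the
#' normal-approximation Wald statistic, so information sharing across
#' features keeps the test calibrated; `dispersion = "per_feature"`
#' exposes the unsmoothed estimate. The Wald statistic is the fold
#' change over its delta-method standard error, compared against the
#' standard normal, with Benjamini-Hochberg adjustment across features.
#' This pipeline is deliberately simple and is not numerically identical
#' to DESeq2 (no shrinkage, outlier handling or independent filtering).
#'
#' @param counts Count matrix or tibble (see [size_factors()]).
#' @param design Data frame with columns `sample` and `group`; samples
#'   must match the count columns.
#' @param group_a,group_b The two group labels to compare (defaults: the
#'   first two groups in `design` order); the fold change is B over A.
#' @param dispersion `"trended"` (default) or `"per_feature"`.
#' @return An object of class `nb_diff`; `tidy()` returns the per-feature
#'   results tibble (`feature`, `base_mean`, `mu_a`, `mu_b`,
#'   `log2_fold_change`, `dispersion`, `stat`, `p_value`, `p_adjusted`).
#' @export
nb_wald_test <- function(counts, design, group_a = NULL, group_b = NULL,
                         dispersion = c("trended", "per_feature")) {
  dispersion <- match.arg(dispersion)
  mat <- count_input(counts)
  design <- tibble::as_tibble(design)
  if (!all(c("sample", "group") %in% names(design))) {
    stop("design needs columns sample and group", call. = FALSE)
  }
  if (!all(design$sample %in% colnames(mat))) {
    stop("design samples missing from count matrix", call. = FALSE)
  }
  groups <- unique(design$group)
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- groups[2]
  sa <- design$sample[design$group == group_a]
  sb <- design$sample[design$group == group_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("each group needs at least 2 samples for dispersion estimation",
         call. = FALSE)
  }
  sub <- mat[, c(sa, sb), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  na <- length(sa)
  nb <- length(sb)
  xa <- norm[, sa, drop = FALSE]
  xb <- norm[, sb, drop = FALSE]
  mu_a <- rowMeans(xa)
  mu_b <- rowMeans(xb)
  base_mean <- rowMeans(norm)
  s2 <- (rowSums((xa - mu_a)^2) + rowSums((xb - mu_b)^2)) / (na + nb - 2)
  xi <- mean(1 / sf) # Poisson term inflation from dividing by size factors
  m <- (na * mu_a + nb * mu_b) / (na + nb)
  alpha_raw <- ifelse(m > 0, (s2 - xi * m) / m^2, NA_real_)
  alpha <- switch(dispersion,
    per_feature = pmax(alpha_raw, 1e-8),
    trended = fit_dispersion_trend(alpha_raw, m)
  )
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  var_mu <- function(mu, n) (xi * mu + alpha * mu^2) / n
  se2 <- (1 / log(2))^2 * (var_mu(mu_a, na) / (mu_a + 0.5)^2 +
                             var_mu(mu_b, nb) / (mu_b + 0.5)^2)
  se <- sqrt(se2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(stat)), 1)
  res <- tibble::tibble(
    feature = rownames(mat),
    base_mean = base_mean,
    mu_a = mu_a,
    mu_b = mu_b,
    log2_fold_change = lfc,
    dispersion = alpha,
    stat = stat,
    p_value = p,
    p_adjusted = p.adjust(p, method = "BH")
  )
  out <- list(results = res, size_factors = sf,
              group_a = group_a, group_b = group_b,
              dispersion_method = dispersion)
  class(out) <- "nb_diff"
  out
}

# Smooth per-feature moment dispersions with an alpha(mu) = a + b/mu
# trend fitted by least squares on trimmed raw estimates.
fit_dispersion_trend <- function(alpha_raw, m) {
  ok <- is.finite(alpha_raw) & m > 0
  fallback <- max(median(pmax(alpha_raw[ok], 0), na.rm = TRUE), 1e-8)
  if (sum(ok) < 10) {
    return(rep(if (is.finite(fallback)) fallback else 1e-8,
               length(alpha_raw)))
  }
  # trim extreme raw estimates so a few outliers cannot tilt the trend
  lo <- stats::quantile(alpha_raw[ok], 0.01)
  hi <- stats::quantile(alpha_raw[ok], 0.99)
  y <- pmin(pmax(alpha_raw[ok], lo), hi)
  fit <- tryCatch(lm(y ~ I(1 / m[ok])), error = function(e) NULL)
  if (is.null(fit)) return(rep(fallback, length(alpha_raw)))
  a <- coef(fit)[1]
  b <- coef(fit)[2]
  pred <- a + b / pmax(m, 1e-8)
  pred[!is.finite(pred)] <- fallback
  pmax(pred, 1e-8)
}

#' @export
print.nb_diff <- function(x, ...) {
  cat("<nb_diff>", nrow(x$results), "features;",
      x$group_b, "vs", x$group_a,
      "| dispersion:", x$dispersion_method, "\n")
  cat("  BH-significant at 0.05:",
      sum(x$results$p_adjusted < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}

#' @rdname nb_wald_test
#' @param x An `nb_diff` object.
#' @param ... Unused.
#' @method tidy nb_diff
#' @export
tidy.nb_diff <- function(x, ...) x$results

#' @rdname nb_wald_test
#' @method glance nb_diff
#' @export
glance.nb_diff <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_significant = sum(x$results$p_adjusted < 0.05, na.rm = TRUE),
    median_dispersion = median(x$results$dispersion),
    dispersion_method = x$dispersion_method
  )
}

#' @method autoplot nb_diff
#' @export
autoplot.nb_diff <- function(object, alpha = 0.05, ...) {
  d <- object$results
  d$significant <- !is.na(d$p_adjusted) & d$p_adjusted < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$base_mean + 1),
                                  y = .data$log2_fold_change,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 mean normalised count",
                  y = "log2 fold change",
                  colour = paste("padj <", alpha)) +
    ggplot2::theme_minimal()
}

#' Transcripts per million
#'
#' Per-sample length-normalised expression:
#' `rate = count / (length / 1000)`; `TPM = rate / sum(rate) * 1e6`,
#' so every sample column sums to one million.
#'
#' @param counts Count matrix or tibble (see [size_factors()]).
#' @param lengths Feature lengths in bp: a named vector or a data frame
#'   with feature ids in the first column and lengths in the second.
#' @return Tibble with a `feature` column and one TPM column per sample.
#' @export
compute_tpm <- function(counts, lengths) {
  mat <- count_input(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  }
  if (!all(rownames(mat) %in% names(lengths))) {
    stop("lengths must cover every feature", call. = FALSE)
  }
  len <- lengths[rownames(mat)]
  if (any(len <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  rate <- mat / (len / 1000)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("sample(s) with zero total rate: ",
         paste(colnames(mat)[totals == 0], collapse = ", "), call. = FALSE)
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  tibble::as_tibble(tpm, rownames = "feature")
}

#' Call differentially expressed genes by printed thresholds
#'
#' A gene is called when (i) the larger of its two group-mean TPMs
#' exceeds `tpm_min`, (ii) the TPM fold change (with a 0.5 pseudocount)
#' exceeds `fc_min` in either direction, and (iii) the NB p-value is
#' below `p_max`. All three comparisons are strict.
#'
#' @param diff An [nb_wald_test()] result (or its `tidy()` tibble).
#' @param tpm A [compute_tpm()] tibble.
#' @param design Data frame with `sample`, `group`.
#' @param group_a,group_b Group labels; defaults taken from `diff` when
#'   it is an `nb_diff` object.
#' @param tpm_min,fc_min,p_max Thresholds (defaults 5, 3, 0.05).
#' @return Tibble of called genes with group-mean TPMs, `fold_change`
#'   (B over A, ratio scale), `p_value` and `direction`
#'   (`"up_in_b"` / `"up_in_a"`).
#' @export
call_differential_genes <- function(diff, tpm, design,
                                    group_a = NULL, group_b = NULL,
                                    tpm_min = 5, fc_min = 3, p_max = 0.05) {
  if (inherits(diff, "nb_diff")) {
    if (is.null(group_a)) group_a <- diff$group_a
    if (is.null(group_b)) group_b <- diff$group_b
    diff <- diff$results
  }
  design <- tibble::as_tibble(design)
  sa <- design$sample[design$group == group_a]
  sb <- design$sample[design$group == group_b]
  if (!all(diff$feature %in% tpm$feature)) {
    stop("missing TPM for tested feature(s)", call. = FALSE)
  }
  tpm_sub <- tpm[match(diff$feature, tpm$feature), ]
  tpm_a <- rowMeans(tpm_sub[, sa, drop = FALSE])
  tpm_b <- rowMeans(tpm_sub[, sb, drop = FALSE])
  fc <- (tpm_b + 0.5) / (tpm_a + 0.5)
  called <- pmax(tpm_a, tpm_b) > tpm_min &
    (fc > fc_min | fc < 1 / fc_min) &
    diff$p_value < p_max
  out <- tibble::tibble(
    feature = diff$feature,
    tpm_a = tpm_a,
    tpm_b = tpm_b,
    fold_change = fc,
    log2_fold_change = diff$log2_fold_change,
    p_value = diff$p_value,
    p_adjusted = diff$p_adjusted,
    direction = ifelse(fc > 1, "up_in_b", "up_in_a")
  )
  out[called, ]
}

#' Expand merged peaks into differential-accessibility windows
#'
#' @param merged Output of [merge_peaks()] (or any interval table).
#' @param halfwidth Window half-width in bp (default 500).
#' @return Interval tibble of `center +/- halfwidth` windows with a
#'   `window_id` column.
#' @export
dar_windows <- function(merged, halfwidth = 500) {
  merged <- as_peak_tbl(merged)
  tibble::tibble(
    window_id = sprintf("window_%05d", seq_len(nrow(merged))),
    chrom = merged$chrom,
    start = pmax(merged$center - as.integer(halfwidth), 0L),
    end = merged$center + as.integer(halfwidth) + 1L,
    center = merged$center
  )
}

#' Call differentially accessible regions
#'
#' Runs [nb_wald_test()] on per-window counts and returns the windows
#' with BH-adjusted p-value below `alpha`, labelled with the condition
#' of higher accessibility.
#'
#' @param counts Window count matrix or tibble (windows x samples).
#' @param design Data frame with `sample`, `group`.
#' @param group_a,group_b Group labels (defaults: first two in design).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param ... Passed to [nb_wald_test()].
#' @return Tibble of DARs (subset of the test results) with a
#'   `higher_in` column; the full results are attached as the
#'   `"results"` attribute.
#' @export
call_dars <- function(counts, design, group_a = NULL, group_b = NULL,
                      alpha = 0.05, ...) {
  fit <- nb_wald_test(counts, design, group_a, group_b, ...)
  res <- fit$results
  res$higher_in <- ifelse(res$log2_fold_change > 0, fit$group_b, fit$group_a)
  dars <- res[!is.na(res$p_adjusted) & res$p_adjusted < alpha, ]
  message("call_dars: ", nrow(dars), " of ", nrow(res),
          " windows at padj < ", alpha)
  attr(dars, "results") <- res
  dars
}
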