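#' Classify condition-specific binding sites
#'
#' Partitions two condition-specific peak sets into the three classes
#' used to describe a transcription-factor binding switch: sites bound
#' only in the first (low) condition are *lost* (set 1), sites bound in
#' both conditions under the center-distance rule are *switch* (set 2),
#' and sites bound only in the second (high) condition are *de novo*
#' (set 3). Matching is delegated to [match_peak_sets()], so the
#' partition is one-to-one and reconciles exactly with the input sizes:
#' `|lost| + |switch|` equals the number of low-condition peaks and
#' `|de novo| + |switch|` the number of high-condition peaks.
#'
#' @param low_peaks Peaks from the first (e.g. low-signalling) condition.
#' @param high_peaks Peaks from the second (high) condition.
#' @param threshold Center-distance threshold in bp (default 150).
#' @return An object of class `site_classification`: a list with tibbles
#'   `lost`, `switch` (one row per matched pair), `denovo`, and the
#'   `threshold`.
#' @examples
#' low <- data.frame(chrom = "chr1", start = c(900, 4900),
#'                   end = c(1100, 5100))
#' high <- data.frame(chrom = "chr1", start = c(1000, 8900),
#'                    end = c(1200, 9100))
#' classify_sites(low, high)
#' @export
classify_sites <- function(low_peaks, high_peaks, threshold = 150) {
  low_peaks <- as_peak_tbl(low_peaks, prefix = "low")
  high_peaks <- as_peak_tbl(high_peaks, prefix = "high")
  m <- match_peak_sets(low_peaks, high_peaks, threshold)
  switch_pairs <- dplyr::left_join(
    m$matched,
    dplyr::rename(low_peaks, peak_a = "peak_id"),
    by = c("peak_a", "chrom")
  )
  out <- list(
    lost = m$unique_a,
    switch = switch_pairs,
    denovo = m$unique_b,
    threshold = threshold
  )
  class(out) <- "site_classification"
  out
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification> threshold:", x$threshold, "bp\n")
  cat("  set 1 (lost):   ", nrow(x$lost), "\n")
  cat("  set 2 (switch): ", nrow(x$switch), "\n")
  cat("  set 3 (de novo):", nrow(x$denovo), "\n")
  invisible(x)
}

#' @method glance site_classification
#' @export
glance.site_classification <- function(x, ...) {
  tibble::tibble(
    n_lost = nrow(x$lost),
    n_switch = nrow(x$switch),
    n_denovo = nrow(x$denovo),
    n_low = nrow(x$lost) + nrow(x$switch),
    n_high = nrow(x$denovo) + nrow(x$switch),
    threshold = x$threshold
  )
}

#' @describeIn classify_sites One row per classified site with a `class`
#'   column (`lost`, `switch`, `denovo`); switch rows carry both peak ids.
#' @param x A `site_classification`.
#' @param ... Unused.
#' @method tidy site_classification
#' @export
tidy.site_classification <- function(x, ...) {
  lost <- dplyr::mutate(
    dplyr::select(x$lost, "peak_id", "chrom", "center"), class = "lost")
  sw <- dplyr::select(x$switch, peak_id = "peak_a", peak_id_high = "peak_b",
                      "chrom", center = "center_a", "distance")
  sw$class <- "switch"
  dn <- dplyr::mutate(
    dplyr::select(x$denovo, "peak_id", "chrom", "center"), class = "denovo")
  dplyr::bind_rows(lost, sw, dn)
}

#' @method autoplot site_classification
#' @export
autoplot.site_classification <- function(object, ...) {
  d <- glance(object)
  dd <- tibble::tibble(
    class = factor(c("set 1\nlost", "set 2\nswitch", "set 3\nde novo"),
                   levels = c("set 1\nlost", "set 2\nswitch",
                              "set 3\nde novo")),
    n = c(d$n_lost, d$n_switch, d$n_denovo)
  )
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "binding sites",
                  title = "Binding-site switch classification") +
    ggplot2::theme_minimal()
}

#' Hypergeometric significance of a peak-set overlap
#'
#' Upper-tail probability of observing at least `n_shared` common sites
#' when two sets of `n_a` and `n_b` sites are drawn at random from a
#' universe of `n_universe` possible sites. Returned on the log10 scale
#' to avoid underflow for genome-scale overlaps.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param n_shared Observed overlap.
#' @param n_universe Number of possible sites.
#' @return One-row tibble with `log10_p` and `p_value` (0 when below
#'   double precision).
#' @examples
#' overlap_significance(5, 5, 5, 100) # log10 p ~ -7.88
#' @export
overlap_significance <- function(n_a, n_b, n_shared, n_universe) {
  if (n_shared > min(n_a, n_b) || max(n_a, n_b) > n_universe ||
      any(c(n_a, n_b, n_shared, n_universe) < 0)) {
    stop("inconsistent counts: need n_shared <= min(n_a, n_b) <= n_universe",
         call. = FALSE)
  }
  log_p <- phyper(n_shared - 1, n_a, n_universe - n_a, n_b,
                  lower.tail = FALSE, log.p = TRUE)
  tibble::tibble(log10_p = log_p / log(10), p_value = exp(log_p))
}

#' Motif-stratified overlap fractions
#'
#' Among low-condition peaks carrying a predicted motif, the fraction
#' that matched a high-condition peak (i.e. fell in the switch class),
#' and the same fraction among peaks without a motif. A binding-factor
#' switch acting through the motif shows a much higher matched fraction
#' in the motif-positive stratum.
#'
#' @param classification A [classify_sites()] result whose low-condition
#'   peaks carry a logical `motif_hit` column (the `lost` table and the
#'   low-side columns of `switch`).
#' @return One-row tibble with counts per stratum and
#'   `fraction_with_motif`, `fraction_without_motif` (NA when a stratum
#'   is empty).
#' @export
motif_stratified_overlap <- function(classification) {
  lost <- classification$lost
  sw <- classification$switch
  if (!"motif_hit" %in% names(lost) || !"motif_hit" %in% names(sw) ||
      anyNA(lost$motif_hit) || anyNA(sw$motif_hit)) {
    stop("every low-condition peak must carry a motif_hit flag",
         call. = FALSE)
  }
  n_with <- sum(lost$motif_hit) + sum(sw$motif_hit)
  n_without <- sum(!lost$motif_hit) + sum(!sw$motif_hit)
  matched_with <- sum(sw$motif_hit)
  matched_without <- sum(!sw$motif_hit)
  tibble::tibble(
    n_with_motif = n_with,
    n_without_motif = n_without,
    matched_with_motif = matched_with,
    matched_without_motif = matched_without,
    fraction_with_motif = ifelse(n_with > 0, matched_with / n_with, NA_real_),
    fraction_without_motif = ifelse(n_without > 0,
                                    matched_without / n_without, NA_real_)
  )
}
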