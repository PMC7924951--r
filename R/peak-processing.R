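#' Build a tag table
#'
#' A tag table holds the mapped positions of a sequencing library (one
#' position per aligned read, the 5' end as reported upstream) together
#' with the library size and the effective genome length used for
#' fold-enrichment normalisation.
#'
#' @param positions Data frame with columns `chrom` and `pos` (bp).
#' @param total_tags Total mapped reads in the library. Defaults to the
#'   number of stored positions; it may be larger (positions can be a
#'   subset) but never smaller.
#' @param genome_size Effective genome length in bp.
#' @return A tibble of class `tag_tbl`, sorted by chromosome and
#'   position, with attributes `total_tags` and `genome_size`.
#' @examples
#' tag_table(data.frame(chrom = "chr1", pos = c(100, 200, 600)),
#'           genome_size = 1e6)
#' @export
tag_table <- function(positions, total_tags = NULL, genome_size) {
  positions <- tibble::as_tibble(positions)
  if (!all(c("chrom", "pos") %in% names(positions))) {
    stop("positions must have columns chrom and pos", call. = FALSE)
  }
  if (is.null(total_tags)) total_tags <- nrow(positions)
  if (total_tags < nrow(positions) || nrow(positions) == 0) {
    stop("total_tags must be >= number of stored positions (> 0)",
         call. = FALSE)
  }
  if (genome_size <= 0) stop("genome_size must be > 0", call. = FALSE)
  positions <- dplyr::arrange(positions, .data$chrom, .data$pos)
  structure(positions, total_tags = as.numeric(total_tags),
            genome_size = as.numeric(genome_size),
            class = c("tag_tbl", class(positions)))
}

#' Count tags in fixed windows around peak centers
#'
#' Counts, for each window center, the tag positions `p` with
#' `|p - center| <= halfwidth`. Windows are independent: a tag may be
#' counted in two overlapping windows. Chromosomes absent from the tag
#' table yield a count of 0 with a warning.
#'
#' @param tags A [tag_table()].
#' @param centers Interval table (coerced via [as_peak_tbl()]); the
#'   `center` column defines the window midpoints.
#' @param halfwidth Window half-width in bp (default 250, i.e. a
#'   501 bp window).
#' @return The `centers` tibble with an added `count` column.
#' @export
count_window_tags <- function(tags, centers, halfwidth = 250) {
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  centers <- as_peak_tbl(centers)
  by_chrom <- split(tags$pos, tags$chrom)
  missing_chrom <- setdiff(unique(centers$chrom), names(by_chrom))
  if (length(missing_chrom) > 0) {
    warning("chromosome(s) absent from tag table: ",
            paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  centers$count <- vapply(seq_len(nrow(centers)), function(i) {
    pos <- by_chrom[[centers$chrom[i]]]
    if (is.null(pos)) return(0L)
    c0 <- centers$center[i]
    # positions are sorted: count via binary search on both edges
    lo <- findInterval(c0 - halfwidth - 0.5, pos)
    hi <- findInterval(c0 + halfwidth + 0.5, pos)
    as.integer(hi - lo)
  }, integer(1))
  centers
}

#' Windowed fold enrichment
#'
#' Fold enrichment is the observed tag density in a window relative to
#' the genome-average density:
#' `FE = (count / window_len) / (total_tags / genome_size)`.
#' A window containing exactly its background expectation has FE = 1.
#'
#' @param count Tag count(s) in the window.
#' @param window_len Window length in bp (a +/-250 bp window spans
#'   501 positions).
#' @param total_tags Library size.
#' @param genome_size Effective genome length in bp.
#' @return Numeric vector of fold enrichments.
#' @examples
#' fold_enrichment(100, 501, 1e7, 2.7e9) # ~53.9
#' @export
fold_enrichment <- function(count, window_len, total_tags, genome_size) {
  if (any(window_len <= 0)) stop("window_len must be > 0", call. = FALSE)
  if (any(total_tags <= 0)) stop("total_tags must be > 0", call. = FALSE)
  if (any(genome_size <= 0)) stop("genome_size must be > 0", call. = FALSE)
  (count / window_len) / (total_tags / genome_size)
}

#' Add per-replicate fold-enrichment columns to a peak table
#'
#' For each replicate tag table, counts tags in `+/- halfwidth` windows
#' around every peak center and converts the counts to fold enrichment,
#' storing the result in columns `fe_1`, `fe_2`, ... .
#'
#' @param peaks Peak table.
#' @param tag_tables List of [tag_table()] objects, one per replicate.
#' @param halfwidth Window half-width in bp (default 250).
#' @return The peak tibble with one `fe_<k>` column per replicate.
#' @export
peak_replicate_fe <- function(peaks, tag_tables, halfwidth = 250) {
  peaks <- as_peak_tbl(peaks)
  window_len <- 2 * halfwidth + 1
  for (k in seq_along(tag_tables)) {
    tt <- tag_tables[[k]]
    counted <- count_window_tags(tt, peaks, halfwidth)
    peaks[[paste0("fe_", k)]] <- fold_enrichment(
      counted$count, window_len,
      attr(tt, "total_tags"), attr(tt, "genome_size"))
  }
  peaks
}

fe_matrix <- function(peaks, n_required = NULL) {
  fe <- fe_cols(peaks)
  if (length(fe) == 0) {
    stop("peak table carries no fold-enrichment (fe_<k>) columns",
         call. = FALSE)
  }
  if (!is.null(n_required) && length(fe) != n_required) {
    stop("expected ", n_required, " fold-enrichment columns, found ",
         length(fe), call. = FALSE)
  }
  as.matrix(peaks[fe])
}

#' Reproducibility filter for ChIP-seq peaks
#'
#' Retains peaks with `q_value < q_max` and fold enrichment strictly
#' greater than `fe_min` in every replicate. Input order is preserved.
#'
#' @param peaks Peak table with a `q_value` column and `fe_<k>` columns.
#' @param q_max Significance cutoff on the probability scale
#'   (default 1e-4; retention requires `q_value < q_max`).
#' @param fe_min Fold-enrichment cutoff (default 10; strict `>`).
#' @return The retained peaks.
#' @export
filter_chip_peaks <- function(peaks, q_max = 1e-4, fe_min = 10) {
  peaks <- as_peak_tbl(peaks)
  if (!"q_value" %in% names(peaks) || anyNA(peaks$q_value)) {
    stop("every peak must carry a q_value", call. = FALSE)
  }
  fe <- fe_matrix(peaks)
  keep <- peaks$q_value < q_max & apply(fe > fe_min, 1, all)
  message("filter_chip_peaks: retained ", sum(keep), " of ", nrow(peaks))
  peaks[keep, ]
}

#' Strong-peak filter
#'
#' Further restricts an already reproducible peak set to strong peaks:
#' fold enrichment strictly greater than `fe_min` in every replicate.
#'
#' @param peaks Peak table with `fe_<k>` columns.
#' @param fe_min Fold-enrichment cutoff (default 20; strict `>`).
#' @return The retained peaks.
#' @export
filter_strong_peaks <- function(peaks, fe_min = 20) {
  peaks <- as_peak_tbl(peaks)
  if (nrow(peaks) == 0) return(peaks)
  fe <- fe_matrix(peaks)
  keep <- apply(fe > fe_min, 1, all)
  message("filter_strong_peaks: retained ", sum(keep), " of ", nrow(peaks))
  peaks[keep, ]
}

#' Reproducibility filter for ATAC-seq peaks
#'
#' Retains peaks whose fold enrichment exceeds `fe_min` in all
#' `n_replicates` replicates (strict `>`); the peak table must carry
#' exactly that many fold-enrichment columns.
#'
#' @param peaks Peak table with `fe_<k>` columns.
#' @param fe_min Fold-enrichment cutoff (default 3).
#' @param n_replicates Required number of replicates (default 3).
#' @return The retained peaks.
#' @export
filter_atac_peaks <- function(peaks, fe_min = 3, n_replicates = 3) {
  peaks <- as_peak_tbl(peaks)
  fe <- fe_matrix(peaks, n_required = n_replicates)
  if (anyNA(fe)) stop("missing fold-enrichment values", call. = FALSE)
  keep <- apply(fe > fe_min, 1, all)
  message("filter_atac_peaks: retained ", sum(keep), " of ", nrow(peaks))
  peaks[keep, ]
}
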