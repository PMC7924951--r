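#' Analysis configuration with the standard thresholds
#'
#' Central container for every threshold used by the two end-to-end
#' pipelines; each value appears exactly once here. Defaults are the
#' conventional published cutoffs for this kind of analysis: ChIP
#' q-value < 1e-4 with fold enrichment > 10 in every replicate (> 20
#' for the strong set), 150 bp center-overlap, ATAC fold enrichment > 3
#' in all 3 replicates, +/-500 bp accessibility windows, TPM > 5 /
#' fold change > 3 / p < 0.05 for differential expression, 10 kb loop
#' anchor matching, 5 kb peak-to-anchor and 15 kb TSS-to-anchor rules.
#'
#' @param q_max,fe_min,fe_strong ChIP filter thresholds.
#' @param overlap_bp Center-distance matching threshold in bp.
#' @param atac_fe_min,atac_n_replicates ATAC reproducibility filter.
#' @param dar_window DAR window half-width in bp.
#' @param dar_alpha Adjusted-p cutoff for DAR calling.
#' @param tpm_min,fc_min,p_max Differential-expression thresholds.
#' @param loop_tol,peak_anchor_tol,tss_anchor_tol Loop-matching and
#'   connectivity tolerances in bp.
#' @param strong_only Restrict switch classification to the strong
#'   (fold enrichment > `fe_strong`) peak set.
#' @param seed Seed recorded in pipeline summaries.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(q_max = 1e-4, fe_min = 10, fe_strong = 20,
                            overlap_bp = 150, atac_fe_min = 3,
                            atac_n_replicates = 3, dar_window = 500,
                            dar_alpha = 0.05, tpm_min = 5, fc_min = 3,
                            p_max = 0.05, loop_tol = 10000,
                            peak_anchor_tol = 5000, tss_anchor_tol = 15000,
                            strong_only = TRUE, seed = 1) {
  cfg <- list(q_max = q_max, fe_min = fe_min, fe_strong = fe_strong,
              overlap_bp = overlap_bp, atac_fe_min = atac_fe_min,
              atac_n_replicates = atac_n_replicates,
              dar_window = dar_window, dar_alpha = dar_alpha,
              tpm_min = tpm_min, fc_min = fc_min, p_max = p_max,
              loop_tol = loop_tol, peak_anchor_tol = peak_anchor_tol,
              tss_anchor_tol = tss_anchor_tol, strong_only = strong_only,
              seed = seed)
  thresholds <- unlist(cfg[setdiff(names(cfg), c("strong_only", "seed"))])
  if (any(thresholds <= 0)) {
    stop("every threshold must be > 0", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in setdiff(names(x), "seed")) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-18s %s\n", "seed", x$seed))
  invisible(x)
}

#' End-to-end binding-site switch analysis
#'
#' Composes the ChIP stages: reproducibility filter (q-value and
#' per-replicate fold enrichment), optional strong-peak filter,
#' center-distance classification into lost / switch / de novo, and,
#' when the low-condition peaks carry motif flags, the motif-stratified
#' overlap fractions.
#'
#' @param low_peaks,high_peaks Peak tables with `q_value` and `fe_<k>`
#'   columns.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: writes one BED file per
#'   class, a pair TSV and a JSON summary.
#' @return List with `classification` (a `site_classification`),
#'   `stratified` (tibble or `NULL`), and `summary` (one-row tibble).
#' @export
run_switch_pipeline <- function(low_peaks, high_peaks,
                                config = pipeline_config(),
                                out_dir = NULL) {
  low <- filter_chip_peaks(low_peaks, config$q_max, config$fe_min)
  high <- filter_chip_peaks(high_peaks, config$q_max, config$fe_min)
  if (config$strong_only) {
    low <- filter_strong_peaks(low, config$fe_strong)
    high <- filter_strong_peaks(high, config$fe_strong)
  }
  cls <- classify_sites(low, high, config$overlap_bp)
  stratified <- if ("motif_hit" %in% names(low) &&
                    !anyNA(low$motif_hit)) {
    motif_stratified_overlap(cls)
  } else {
    NULL
  }
  summary <- dplyr::bind_cols(
    glance(cls),
    tibble::tibble(n_low_input = nrow(tibble::as_tibble(low_peaks)),
                   n_high_input = nrow(tibble::as_tibble(high_peaks)))
  )
  if (!is.null(stratified)) summary <- dplyr::bind_cols(summary, stratified)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(cls$lost, file.path(out_dir, "set1_lost.bed"))
    write_bed(cls$denovo, file.path(out_dir, "set3_denovo.bed"))
    low_sw <- as_peak_tbl(data.frame(
      chrom = cls$switch$chrom,
      start = cls$switch$start, end = cls$switch$end,
      peak_id = cls$switch$peak_a))
    write_bed(low_sw, file.path(out_dir, "set2_switch_low.bed"))
    readr::write_tsv(
      dplyr::select(cls$switch, "peak_a", "peak_b", "chrom",
                    "center_a", "center_b", "distance"),
      file.path(out_dir, "set2_switch_pairs.tsv"))
    jsonlite::write_json(as.list(summary),
                         file.path(out_dir, "switch_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(classification = cls, stratified = stratified, summary = summary)
}

#' End-to-end loop connectivity analysis
#'
#' Compares the two conditions' loop sets under the anchor-distance
#' rule, then runs the peak-to-anchor-to-TSS chain on the induced
#' condition's loops (shared plus condition-specific).
#'
#' @param peaks Peak table for the induced condition (e.g. coactivator
#'   binding sites).
#' @param loops_low,loops_high Condition-level loop tables.
#' @param tss TSS table.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the connection TSV and
#'   JSON summary.
#' @return List with `comparison` (a `loop_comparison`) and `report`
#'   (a `connectivity_report`).
#' @export
run_loop_pipeline <- function(peaks, loops_low, loops_high, tss,
                              config = pipeline_config(),
                              out_dir = NULL) {
  comparison <- compare_condition_loops(loops_low, loops_high,
                                        config$loop_tol)
  report <- connectivity_summary(
    peaks,
    loops_shared = comparison$shared_2,
    loops_specific = comparison$specific_2,
    tss = tss,
    peak_tol = config$peak_anchor_tol,
    tss_tol = config$tss_anchor_tol
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(report$connections,
                     file.path(out_dir, "connections.tsv"))
    jsonlite::write_json(
      c(as.list(glance(comparison)), as.list(glance(report))),
      file.path(out_dir, "connectivity_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(comparison = comparison, report = report)
}
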