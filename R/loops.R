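#' Validate and normalise a chromatin-loop table
#'
#' Loops are tibbles with two anchors: `chrom1`, `start1`, `end1`,
#' `chrom2`, `start2`, `end2` (BEDPE layout). Anchors are reordered so
#' `(chrom1, start1) <= (chrom2, start2)` lexicographically; anchor
#' centers are filled as interval midpoints in `center1` / `center2`.
#' Optional columns: `loop_id`, `condition`, `replicate`.
#'
#' @param x A data frame in BEDPE-like layout.
#' @param prefix Prefix for generated loop ids.
#' @return A validated loop tibble.
#' @export
as_loop_tbl <- function(x, prefix = "loop") {
  x <- tibble::as_tibble(x)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("start1", "end1", "start2", "end2")) {
    x[[col]] <- as.integer(round(x[[col]]))
  }
  if (any(x$start1 >= x$end1) || any(x$start2 >= x$end2) ||
      any(x$start1 < 0) || any(x$start2 < 0)) {
    stop("malformed anchor interval", call. = FALSE)
  }
  swap <- x$chrom2 < x$chrom1 | (x$chrom1 == x$chrom2 & x$start2 < x$start1)
  if (any(swap)) {
    tmp <- x[swap, c("chrom1", "start1", "end1")]
    x[swap, c("chrom1", "start1", "end1")] <-
      x[swap, c("chrom2", "start2", "end2")]
    x[swap, c("chrom2", "start2", "end2")] <- tmp
    message("as_loop_tbl: reordered anchors on ", sum(swap), " loop(s)")
  }
  x$center1 <- as.integer(floor((as.numeric(x$start1) +
                                   as.numeric(x$end1)) / 2))
  x$center2 <- as.integer(floor((as.numeric(x$start2) +
                                   as.numeric(x$end2)) / 2))
  if (!"loop_id" %in% names(x)) {
    x$loop_id <- sprintf("%s_%05d", prefix, seq_len(nrow(x)))
  }
  dplyr::relocate(x, "loop_id")
}

# Cross pairs of loops on the same chromosome pair with both ordered
# anchor centers within tol (no anchor swap across pairs).
loop_candidate_pairs <- function(l1, l2, tol) {
  i1 <- tibble::tibble(idx_1 = seq_len(nrow(l1)), chrom1 = l1$chrom1,
                       chrom2 = l1$chrom2, c1_a = l1$center1,
                       c2_a = l1$center2, s_a = l1$start1)
  i2 <- tibble::tibble(idx_2 = seq_len(nrow(l2)), chrom1 = l2$chrom1,
                       chrom2 = l2$chrom2, c1_b = l2$center1,
                       c2_b = l2$center2, s_b = l2$start1)
  pairs <- dplyr::inner_join(i1, i2, by = c("chrom1", "chrom2"),
                             relationship = "many-to-many")
  pairs$d1 <- abs(as.numeric(pairs$c1_a) - as.numeric(pairs$c1_b))
  pairs$d2 <- abs(as.numeric(pairs$c2_a) - as.numeric(pairs$c2_b))
  pairs[pairs$d1 <= tol & pairs$d2 <= tol, , drop = FALSE]
}

#' Reconcile loops between two replicates
#'
#' A loop from replicate 1 is replicated when some replicate-2 loop on
#' the same chromosome pair has both anchor centers within `tol` bp
#' (inclusive; anchors are compared in order, never swapped). Each
#' replicated loop is annotated with its nearest replicate-2 partner
#' (smallest maximum anchor distance, then smallest sum).
#'
#' @param rep1,rep2 Loop tables (coerced via [as_loop_tbl()]).
#' @param tol Anchor-center tolerance in bp (default 10000).
#' @return The replicated subset of `rep1` with `partner_id`,
#'   `anchor1_distance` and `anchor2_distance` columns.
#' @export
reconcile_replicate_loops <- function(rep1, rep2, tol = 10000) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  rep1 <- as_loop_tbl(rep1, prefix = "rep1")
  rep2 <- as_loop_tbl(rep2, prefix = "rep2")
  pairs <- loop_candidate_pairs(rep1, rep2, tol)
  if (nrow(pairs) == 0) {
    out <- rep1[0, ]
    out$partner_id <- character()
    out$anchor1_distance <- numeric()
    out$anchor2_distance <- numeric()
    return(out)
  }
  best <- pairs |>
    dplyr::mutate(dmax = pmax(.data$d1, .data$d2),
                  dsum = .data$d1 + .data$d2) |>
    dplyr::arrange(.data$idx_1, .data$dmax, .data$dsum, .data$idx_2) |>
    dplyr::distinct(.data$idx_1, .keep_all = TRUE)
  out <- rep1[best$idx_1, ]
  out$partner_id <- rep2$loop_id[best$idx_2]
  out$anchor1_distance <- best$d1
  out$anchor2_distance <- best$d2
  message("reconcile_replicate_loops: ", nrow(out), " of ", nrow(rep1),
          " replicated")
  out
}

#' Compare loop sets between two conditions
#'
#' Classifies loops as shared between conditions or condition-specific
#' using the same anchor-distance rule as replicate reconciliation, with
#' deterministic one-to-one greedy matching (nearest maximum anchor
#' distance first; symmetric under swapping the conditions) so that the
#' partition reconciles exactly with the input sizes.
#'
#' @param cond1,cond2 Loop tables.
#' @param tol Anchor-center tolerance in bp (default 10000).
#' @return An object of class `loop_comparison`: list with `shared`
#'   (matched pairs: the cond1 loop annotated with its cond2 partner),
#'   `shared_2` (the matched cond2 loops), `specific_1`, `specific_2`
#'   and `tol`.
#' @export
compare_condition_loops <- function(cond1, cond2, tol = 10000) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  cond1 <- as_loop_tbl(cond1, prefix = "cond1")
  cond2 <- as_loop_tbl(cond2, prefix = "cond2")
  pairs <- loop_candidate_pairs(cond1, cond2, tol)
  if (nrow(pairs) > 0) {
    ord <- order(pmax(pairs$d1, pairs$d2), pairs$d1 + pairs$d2,
                 pmin(pairs$s_a, pairs$s_b), pmax(pairs$s_a, pairs$s_b))
    pairs <- pairs[ord, ]
    used_1 <- logical(nrow(cond1))
    used_2 <- logical(nrow(cond2))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$idx_1[k]
      j <- pairs$idx_2[k]
      if (!used_1[i] && !used_2[j]) {
        keep[k] <- TRUE
        used_1[i] <- TRUE
        used_2[j] <- TRUE
      }
    }
    pairs <- pairs[keep, ]
  }
  shared <- cond1[pairs$idx_1, ]
  shared$partner_id <- cond2$loop_id[pairs$idx_2]
  shared$anchor1_distance <- pairs$d1
  shared$anchor2_distance <- pairs$d2
  out <- list(
    shared = shared,
    shared_2 = cond2[pairs$idx_2, ],
    specific_1 = cond1[setdiff(seq_len(nrow(cond1)), pairs$idx_1), ],
    specific_2 = cond2[setdiff(seq_len(nrow(cond2)), pairs$idx_2), ],
    tol = tol
  )
  class(out) <- "loop_comparison"
  out
}

#' @export
print.loop_comparison <- function(x, ...) {
  cat("<loop_comparison> tol:", x$tol, "bp\n")
  cat("  shared:        ", nrow(x$shared), "\n")
  cat("  specific to 1: ", nrow(x$specific_1), "\n")
  cat("  specific to 2: ", nrow(x$specific_2), "\n")
  invisible(x)
}

#' @method glance loop_comparison
#' @export
glance.loop_comparison <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x$shared),
    n_specific_1 = nrow(x$specific_1),
    n_specific_2 = nrow(x$specific_2),
    tol = x$tol
  )
}

#' Assign peaks to loop anchors
#'
#' A peak is assigned to a loop anchor when its center lies within `tol`
#' bp (inclusive) of the anchor center on the same chromosome. A peak
#' may be assigned to several loops and to both anchors.
#'
#' @param peaks Peak table.
#' @param loops Loop table.
#' @param tol Distance tolerance in bp (default 5000).
#' @return Tibble of assignments: `peak_id`, `loop_id`, `side` (1 or 2),
#'   `distance`.
#' @export
assign_peaks_to_anchors <- function(peaks, loops, tol = 5000) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  peaks <- as_peak_tbl(peaks)
  loops <- as_loop_tbl(loops)
  pk <- tibble::tibble(peak_id = peaks$peak_id, chrom = peaks$chrom,
                       peak_center = peaks$center)
  one_side <- function(side) {
    an <- tibble::tibble(
      loop_id = loops$loop_id,
      chrom = loops[[paste0("chrom", side)]],
      anchor_center = loops[[paste0("center", side)]]
    )
    hits <- dplyr::inner_join(pk, an, by = "chrom",
                              relationship = "many-to-many")
    hits$distance <- abs(as.numeric(hits$peak_center) -
                           as.numeric(hits$anchor_center))
    hits <- hits[hits$distance <= tol, ]
    hits$side <- side
    hits
  }
  out <- dplyr::bind_rows(one_side(1L), one_side(2L))
  dplyr::arrange(
    dplyr::select(out, "peak_id", "loop_id", "side", "distance"),
    .data$peak_id, .data$loop_id, .data$side)
}

#' Connect anchor-assigned peaks to TSSs through the partner anchor
#'
#' For every (peak, loop, side) assignment, finds the TSSs lying within
#' `tol` bp (inclusive) of the center of the *opposite* anchor, on that
#' anchor's chromosome. The TSS search is strand-agnostic.
#'
#' @param assignments Output of [assign_peaks_to_anchors()] on the same
#'   loop set.
#' @param loops Loop table.
#' @param tss TSS table with `gene_id`, `chrom`, `tss` (bp) and
#'   optionally `strand`.
#' @param tol Distance tolerance in bp (default 15000).
#' @return Tibble of connections: `peak_id`, `loop_id`, `side`,
#'   `gene_id`, `tss_distance`.
#' @export
connect_peaks_to_tss <- function(assignments, loops, tss, tol = 15000) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  loops <- as_loop_tbl(loops)
  tss <- tibble::as_tibble(tss)
  if (!all(c("gene_id", "chrom", "tss") %in% names(tss))) {
    stop("tss needs columns gene_id, chrom, tss", call. = FALSE)
  }
  a <- tibble::as_tibble(assignments)
  if (nrow(a) == 0) {
    return(tibble::tibble(peak_id = character(), loop_id = character(),
                          side = integer(), gene_id = character(),
                          tss_distance = numeric()))
  }
  a$other_side <- 3L - a$side
  li <- match(a$loop_id, loops$loop_id)
  if (anyNA(li)) stop("assignments refer to loops absent from the loop set",
                      call. = FALSE)
  a$other_chrom <- ifelse(a$other_side == 1L, loops$chrom1[li],
                          loops$chrom2[li])
  a$other_center <- ifelse(a$other_side == 1L, loops$center1[li],
                           loops$center2[li])
  hits <- dplyr::inner_join(
    a, dplyr::rename(tss, other_chrom = "chrom"),
    by = "other_chrom", relationship = "many-to-many")
  hits$tss_distance <- abs(as.numeric(hits$tss) -
                             as.numeric(hits$other_center))
  hits <- hits[hits$tss_distance <= tol, ]
  dplyr::arrange(
    dplyr::select(hits, "peak_id", "loop_id", "side", "gene_id",
                  "tss_distance"),
    .data$peak_id, .data$loop_id, .data$gene_id)
}

#' Peak-to-anchor-to-TSS connectivity report
#'
#' Runs the full connectivity chain on the union of shared
#' (condition-conserved) and condition-specific loops: peaks are placed
#' on loop anchors ([assign_peaks_to_anchors()]), then connected to TSSs
#' through the partner anchor ([connect_peaks_to_tss()]). Each
#' TSS-connected peak is attributed to the conserved class when at least
#' one of its connecting loops is shared, otherwise to the specific
#' class. Percentages are the successive ratios of the chain, rounded to
#' the nearest integer (raw ratios are retained).
#'
#' @param peaks Peak table (e.g. coactivator-associated sites in the
#'   induced condition).
#' @param loops_shared Loops present in both conditions.
#' @param loops_specific Loops specific to the condition of interest.
#' @param tss TSS table.
#' @param peak_tol Peak-to-anchor tolerance in bp (default 5000).
#' @param tss_tol TSS-to-anchor tolerance in bp (default 15000).
#' @return An object of class `connectivity_report`: counts,
#'   percentages, raw fractions and the per-connection records.
#' @export
connectivity_summary <- function(peaks, loops_shared, loops_specific, tss,
                                 peak_tol = 5000, tss_tol = 15000) {
  peaks <- as_peak_tbl(peaks)
  loops_shared <- as_loop_tbl(loops_shared, prefix = "shared")
  loops_specific <- as_loop_tbl(loops_specific, prefix = "specific")
  if (length(intersect(loops_shared$loop_id, loops_specific$loop_id)) > 0) {
    loops_shared$loop_id <- paste0("shared:", loops_shared$loop_id)
    loops_specific$loop_id <- paste0("specific:", loops_specific$loop_id)
  }
  loops_shared$loop_class <- "conserved"
  loops_specific$loop_class <- "specific"
  loops <- dplyr::bind_rows(loops_shared, loops_specific)
  assignments <- if (nrow(loops) > 0) {
    assign_peaks_to_anchors(peaks, loops, peak_tol)
  } else {
    tibble::tibble(peak_id = character(), loop_id = character(),
                   side = integer(), distance = numeric())
  }
  connections <- if (nrow(assignments) > 0) {
    connect_peaks_to_tss(assignments, loops, tss, tss_tol)
  } else {
    tibble::tibble(peak_id = character(), loop_id = character(),
                   side = integer(), gene_id = character(),
                   tss_distance = numeric())
  }
  connections$loop_class <-
    loops$loop_class[match(connections$loop_id, loops$loop_id)]
  n_total <- dplyr::n_distinct(peaks$peak_id)
  n_in_anchors <- dplyr::n_distinct(assignments$peak_id)
  connected <- unique(connections$peak_id)
  n_tss <- length(connected)
  via_conserved <- unique(
    connections$peak_id[connections$loop_class == "conserved"])
  n_conserved <- length(via_conserved)
  n_specific <- n_tss - n_conserved
  frac <- function(num, den) if (den > 0) num / den else 0
  out <- list(
    n_peaks_total = n_total,
    n_peaks_in_anchors = n_in_anchors,
    n_peaks_tss_connected = n_tss,
    n_via_conserved_loops = n_conserved,
    n_via_specific_loops = n_specific,
    fraction_in_anchors = frac(n_in_anchors, n_total),
    fraction_tss_connected = frac(n_tss, n_in_anchors),
    fraction_via_conserved = frac(n_conserved, n_tss),
    pct_in_anchors = round(100 * frac(n_in_anchors, n_total)),
    pct_tss_connected = round(100 * frac(n_tss, n_in_anchors)),
    pct_via_conserved = round(100 * frac(n_conserved, n_tss)),
    assignments = assignments,
    connections = connections,
    peak_tol = peak_tol,
    tss_tol = tss_tol
  )
  class(out) <- "connectivity_report"
  out
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("<connectivity_report>\n")
  cat(sprintf("  peaks total:          %d\n", x$n_peaks_total))
  cat(sprintf("  in loop anchors:      %d (%d%%)\n",
              x$n_peaks_in_anchors, x$pct_in_anchors))
  cat(sprintf("  connected to a TSS:   %d (%d%%)\n",
              x$n_peaks_tss_connected, x$pct_tss_connected))
  cat(sprintf("  via conserved loops:  %d (%d%%)\n",
              x$n_via_conserved_loops, x$pct_via_conserved))
  cat(sprintf("  via specific loops:   %d\n", x$n_via_specific_loops))
  invisible(x)
}

#' @rdname connectivity_summary
#' @param x A `connectivity_report`.
#' @param ... Unused.
#' @method tidy connectivity_report
#' @export
tidy.connectivity_report <- function(x, ...) x$connections

#' @rdname connectivity_summary
#' @method glance connectivity_report
#' @export
glance.connectivity_report <- function(x, ...) {
  tibble::tibble(
    n_peaks_total = x$n_peaks_total,
    n_peaks_in_anchors = x$n_peaks_in_anchors,
    n_peaks_tss_connected = x$n_peaks_tss_connected,
    n_via_conserved_loops = x$n_via_conserved_loops,
    n_via_specific_loops = x$n_via_specific_loops,
    pct_in_anchors = x$pct_in_anchors,
    pct_tss_connected = x$pct_tss_connected,
    pct_via_conserved = x$pct_via_conserved
  )
}

#' @method autoplot connectivity_report
#' @export
autoplot.connectivity_report <- function(object, ...) {
  d <- tibble::tibble(
    stage = factor(c("all peaks", "in anchors", "TSS-connected",
                     "via conserved"),
                   levels = c("all peaks", "in anchors", "TSS-connected",
                              "via conserved")),
    n = c(object$n_peaks_total, object$n_peaks_in_anchors,
          object$n_peaks_tss_connected, object$n_via_conserved_loops)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "peaks",
                  title = "Peak → anchor → TSS connectivity") +
    ggplot2::theme_minimal()
}
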