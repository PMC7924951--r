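#' Validate and normalise a peak/interval table
#'
#' Peaks and generic genomic intervals are plain tibbles. The required
#' columns are `chrom`, `start` and `end` (0-based half-open, BED
#' convention). A `center` column may be supplied (e.g. a summit from the
#' upstream peak caller); where absent or `NA` it is filled with the
#' interval midpoint `floor((start + end) / 2)`. Optional columns used
#' downstream: `peak_id`, `q_value` (probability scale), `condition`,
#' `motif_hit`, and per-replicate fold-enrichment columns `fe_1`, `fe_2`,
#' ... .
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param prefix Prefix used when `peak_id` has to be generated.
#' @return A tibble with validated coordinates, a filled `center` column
#'   and a `peak_id` column.
#' @examples
#' as_peak_tbl(data.frame(chrom = "chr1", start = 100, end = 300))
#' @export
as_peak_tbl <- function(x, prefix = "peak") {
  x <- tibble::as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$start <- as.integer(round(x$start))
  x$end <- as.integer(round(x$end))
  if (any(x$start < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(x$start >= x$end)) {
    stop("malformed interval: start must be < end", call. = FALSE)
  }
  if (!"center" %in% names(x)) x$center <- NA_integer_
  x$center <- as.integer(round(x$center))
  mid <- as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
  x$center <- ifelse(is.na(x$center), mid, x$center)
  if (any(x$center < x$start | x$center >= x$end)) {
    stop("supplied center must satisfy start <= center < end", call. = FALSE)
  }
  if (!"peak_id" %in% names(x)) {
    x$peak_id <- sprintf("%s_%05d", prefix, seq_len(nrow(x)))
  }
  if ("q_value" %in% names(x)) {
    bad <- !is.na(x$q_value) & (x$q_value < 0 | x$q_value > 1)
    if (any(bad)) stop("q_value must lie in [0, 1]", call. = FALSE)
  }
  fe <- fe_cols(x)
  if (length(fe) > 0) {
    fev <- as.matrix(x[fe])
    if (any(fev < 0, na.rm = TRUE)) {
      stop("fold-enrichment values must be >= 0", call. = FALSE)
    }
  }
  dplyr::relocate(x, "peak_id", "chrom", "start", "end", "center")
}

#' Per-replicate fold-enrichment column names
#'
#' @param x A peak tibble.
#' @return Character vector of columns matching `fe_<k>`.
#' @keywords internal
fe_cols <- function(x) {
  grep("^fe_[0-9]+$", names(x), value = TRUE)
}

#' Center-to-center distance between intervals
#'
#' Distances are computed row-wise between two interval tables of equal
#' length (either may have one row, which is recycled). Intervals on
#' different chromosomes get an infinite distance, the sentinel used by
#' all matching rules in this package.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` and optionally
#'   `center` (see [as_peak_tbl()]).
#' @return Numeric vector of absolute center distances in bp; `Inf` where
#'   chromosomes differ.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 200)
#' b <- data.frame(chrom = "chr1", start = 200, end = 400)
#' center_distance(a, b) # |100 - 300| = 200
#' @export
center_distance <- function(a, b) {
  a <- as_peak_tbl(a)
  b <- as_peak_tbl(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1, nrow(b)), ]
    else if (nrow(b) == 1) b <- b[rep(1, nrow(a)), ]
    else stop("a and b must have equal (or recyclable) numbers of rows",
              call. = FALSE)
  }
  ifelse(a$chrom == b$chrom, abs(as.numeric(a$center) - as.numeric(b$center)),
         Inf)
}

# Deterministic greedy one-to-one matching over candidate pairs.
# Pairs are taken in order of (distance, min start, max start, min center):
# mutual-nearest pairs are accepted first and the tie-break key is
# symmetric under an A/B label swap.
greedy_match_pairs <- function(pairs, n_a, n_b) {
  if (nrow(pairs) == 0) {
    return(pairs)
  }
  ord <- order(pairs$distance,
               pmin(pairs$start_a, pairs$start_b),
               pmax(pairs$start_a, pairs$start_b),
               pmin(pairs$center_a, pairs$center_b))
  pairs <- pairs[ord, ]
  used_a <- logical(n_a)
  used_b <- logical(n_b)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$idx_a[k]
    j <- pairs$idx_b[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  pairs[keep, ]
}

#' Match two peak sets by center distance
#'
#' Implements the center-overlap rule used throughout the package: two
#' peaks are the same site when their centers lie within `threshold` bp
#' (inclusive) on the same chromosome; centers beyond the threshold are
#' unique sites. Matching is one-to-one: candidate pairs are ranked by
#' center distance (ties broken by the lower start coordinate) and
#' accepted greedily, so mutual-nearest pairs win and the output is
#' deterministic and symmetric under swapping the two sets.
#'
#' @param a,b Peak tables (coerced via [as_peak_tbl()]).
#' @param threshold Maximum center distance in bp (default 150).
#' @return An object of class `peak_match`: a list with tibbles
#'   `matched` (one row per pair, with both peak ids and the distance),
#'   `unique_a`, `unique_b`, and the `threshold` used.
#' @examples
#' a <- data.frame(chrom = "chr1", start = c(900, 4900), end = c(1100, 5100))
#' b <- data.frame(chrom = "chr1", start = c(1000, 8900), end = c(1200, 9100))
#' match_peak_sets(a, b)
#' @export
match_peak_sets <- function(a, b, threshold = 150) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  a <- as_peak_tbl(a, prefix = "a")
  b <- as_peak_tbl(b, prefix = "b")
  pairs <- candidate_pairs(a, b, threshold)
  pairs <- greedy_match_pairs(pairs, nrow(a), nrow(b))
  matched <- tibble::tibble(
    peak_a = a$peak_id[pairs$idx_a],
    peak_b = b$peak_id[pairs$idx_b],
    chrom = a$chrom[pairs$idx_a],
    center_a = a$center[pairs$idx_a],
    center_b = b$center[pairs$idx_b],
    distance = pairs$distance,
    idx_a = pairs$idx_a,
    idx_b = pairs$idx_b
  )
  out <- list(
    matched = matched,
    unique_a = a[setdiff(seq_len(nrow(a)), pairs$idx_a), ],
    unique_b = b[setdiff(seq_len(nrow(b)), pairs$idx_b), ],
    threshold = threshold
  )
  class(out) <- "peak_match"
  out
}

# All cross pairs within threshold, same chromosome. O(n*m) within a
# chromosome after a coarse sort-window cut; fine at the scales this
# package targets.
candidate_pairs <- function(a, b, threshold) {
  ia <- tibble::tibble(idx_a = seq_len(nrow(a)), chrom = a$chrom,
                       start_a = a$start, center_a = a$center)
  ib <- tibble::tibble(idx_b = seq_len(nrow(b)), chrom = b$chrom,
                       start_b = b$start, center_b = b$center)
  pairs <- dplyr::inner_join(ia, ib, by = "chrom",
                             relationship = "many-to-many")
  pairs$distance <- abs(as.numeric(pairs$center_a) -
                          as.numeric(pairs$center_b))
  pairs[pairs$distance <= threshold, , drop = FALSE]
}

#' @export
print.peak_match <- function(x, ...) {
  cat("<peak_match> threshold:", x$threshold, "bp\n")
  cat("  matched pairs:", nrow(x$matched), "\n")
  cat("  unique to A:  ", nrow(x$unique_a), "\n")
  cat("  unique to B:  ", nrow(x$unique_b), "\n")
  invisible(x)
}

#' @method glance peak_match
#' @export
glance.peak_match <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x$matched),
    n_unique_a = nrow(x$unique_a),
    n_unique_b = nrow(x$unique_b),
    threshold = x$threshold
  )
}

#' Merge nearby peaks into single intervals
#'
#' Within each chromosome, centers are visited left to right; a peak
#' whose center lies within `threshold` bp (inclusive) of the current
#' merged center is absorbed and the merged coordinate is replaced by the
#' midpoint of the two centers (`floor` on odd sums), applied iteratively
#' along the chain. Output centers are therefore pairwise more than
#' `threshold` apart, which makes the operation idempotent.
#'
#' @param peaks Peak table (coerced via [as_peak_tbl()]).
#' @param threshold Merge distance in bp (default 150).
#' @return Tibble with `chrom`, `start`, `end` (the union span of the
#'   merged members), `center` (the chained midpoint) and `n_merged`.
#' @examples
#' p <- data.frame(chrom = "chr1", start = c(950, 1050, 4950),
#'                 end = c(1050, 1150, 5050))
#' merge_peaks(p) # centers 1000 and 1100 collapse to 1050
#' @export
merge_peaks <- function(peaks, threshold = 150) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  peaks <- as_peak_tbl(peaks)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), center = integer(),
                          n_merged = integer()))
  }
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$center, .data$start)
  out <- peaks |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) merge_chrom(d, threshold)) |>
    dplyr::ungroup()
  dplyr::relocate(out, "chrom", "start", "end", "center", "n_merged")
}

merge_chrom <- function(d, threshold) {
  cur_center <- d$center[1]
  cur_start <- d$start[1]
  cur_end <- d$end[1]
  cur_n <- 1L
  res <- list()
  emit <- function() {
    tibble::tibble(start = cur_start, end = cur_end,
                   center = as.integer(cur_center), n_merged = cur_n)
  }
  for (i in seq_len(nrow(d))[-1]) {
    if (d$center[i] - cur_center <= threshold) {
      cur_center <- floor((cur_center + as.numeric(d$center[i])) / 2)
      cur_start <- min(cur_start, d$start[i])
      cur_end <- max(cur_end, d$end[i])
      cur_n <- cur_n + 1L
    } else {
      res[[length(res) + 1]] <- emit()
      cur_center <- d$center[i]
      cur_start <- d$start[i]
      cur_end <- d$end[i]
      cur_n <- 1L
    }
  }
  res[[length(res) + 1]] <- emit()
  dplyr::bind_rows(res)
}
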