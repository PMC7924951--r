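read_table_checked <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0 || all(!nzchar(lines))) {
    warning("empty ", what, " file: ", path, call. = FALSE)
    return(NULL)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_min_cols)
  if (length(bad) > 0) {
    stop(what, " parse error at line ", bad[1], " of ", path,
         ": expected >= ", n_min_cols, " tab-separated fields",
         call. = FALSE)
  }
  fields
}

num_field <- function(fields, k, path, what, integer = FALSE) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), k)))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop(what, " parse error at line ", bad[1], " of ", path,
         ": column ", k, " is not numeric", call. = FALSE)
  }
  if (integer) as.integer(v) else v
}

chr_field <- function(fields, k) vapply(fields, `[[`, character(1), k)

#' Read a BED file of intervals/peaks
#'
#' Accepts BED3 to BED6; the name column (4) becomes `peak_id` and the
#' strand column (6) is kept when present. Coordinates pass through
#' verbatim (0-based half-open).
#'
#' @param path File path.
#' @return A peak tibble ([as_peak_tbl()]); empty with a warning for an
#'   empty file.
#' @export
read_bed <- function(path) {
  fields <- read_table_checked(path, 3, "BED")
  if (is.null(fields)) {
    return(as_peak_tbl(tibble::tibble(chrom = character(),
                                      start = integer(), end = integer())))
  }
  out <- tibble::tibble(
    chrom = chr_field(fields, 1),
    start = num_field(fields, 2, path, "BED", integer = TRUE),
    end = num_field(fields, 3, path, "BED", integer = TRUE)
  )
  if (all(lengths(fields) >= 4)) out$peak_id <- chr_field(fields, 4)
  if (all(lengths(fields) >= 6)) out$strand <- chr_field(fields, 6)
  as_peak_tbl(out)
}

#' Write intervals/peaks as BED6
#'
#' @param peaks Peak table.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_bed <- function(peaks, path) {
  peaks <- as_peak_tbl(peaks)
  d <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                  0L, if ("strand" %in% names(peaks)) peaks$strand else ".")
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(peaks)
}

#' Read a narrowPeak (ENCODE 10-column) file
#'
#' Column 9 (`-log10` q-value) is converted to the probability scale;
#' column 10 (summit offset from `start`) populates `center` when it is
#' `>= 0`, otherwise the interval midpoint is used. Column 7
#' (signalValue) is kept as `signal_value`.
#'
#' @param path File path.
#' @return A peak tibble with `q_value` and `signal_value` columns.
#' @export
read_narrowpeak <- function(path) {
  fields <- read_table_checked(path, 10, "narrowPeak")
  if (is.null(fields)) {
    return(as_peak_tbl(tibble::tibble(chrom = character(),
                                      start = integer(), end = integer(),
                                      q_value = numeric())))
  }
  start <- num_field(fields, 2, path, "narrowPeak", integer = TRUE)
  summit <- num_field(fields, 10, path, "narrowPeak", integer = TRUE)
  nlq <- num_field(fields, 9, path, "narrowPeak")
  out <- tibble::tibble(
    chrom = chr_field(fields, 1),
    start = start,
    end = num_field(fields, 3, path, "narrowPeak", integer = TRUE),
    peak_id = chr_field(fields, 4),
    strand = chr_field(fields, 6),
    signal_value = num_field(fields, 7, path, "narrowPeak"),
    q_value = ifelse(nlq >= 0, 10^(-nlq), NA_real_),
    center = ifelse(summit >= 0, start + summit, NA_integer_)
  )
  as_peak_tbl(out)
}

#' Write peaks as narrowPeak
#'
#' The summit offset (column 10) is `center - start`; the q-value is
#' written as `-log10(q)` (`-1` when missing).
#'
#' @param peaks Peak table.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- as_peak_tbl(peaks)
  q <- if ("q_value" %in% names(peaks)) peaks$q_value else NA_real_
  d <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$peak_id, 0L,
    if ("strand" %in% names(peaks)) peaks$strand else ".",
    if ("signal_value" %in% names(peaks)) peaks$signal_value else 0,
    -1,
    ifelse(is.na(q), -1, -log10(q)),
    peaks$center - peaks$start
  )
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(peaks)
}

#' Read chromatin loops from a BEDPE file
#'
#' Requires the six coordinate columns; column 7 (name) becomes
#' `loop_id` when present. Anchors are reordered to the canonical
#' orientation with a note (see [as_loop_tbl()]).
#'
#' @param path File path.
#' @return A loop tibble.
#' @export
read_bedpe <- function(path) {
  fields <- read_table_checked(path, 6, "BEDPE")
  if (is.null(fields)) {
    return(as_loop_tbl(tibble::tibble(
      chrom1 = character(), start1 = integer(), end1 = integer(),
      chrom2 = character(), start2 = integer(), end2 = integer())))
  }
  out <- tibble::tibble(
    chrom1 = chr_field(fields, 1),
    start1 = num_field(fields, 2, path, "BEDPE", integer = TRUE),
    end1 = num_field(fields, 3, path, "BEDPE", integer = TRUE),
    chrom2 = chr_field(fields, 4),
    start2 = num_field(fields, 5, path, "BEDPE", integer = TRUE),
    end2 = num_field(fields, 6, path, "BEDPE", integer = TRUE)
  )
  if (all(lengths(fields) >= 7)) out$loop_id <- chr_field(fields, 7)
  as_loop_tbl(out)
}

#' Write loops as BEDPE (7 columns: coordinates + loop id)
#'
#' @param loops Loop table.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  loops <- as_loop_tbl(loops)
  d <- data.frame(loops$chrom1, loops$start1, loops$end1,
                  loops$chrom2, loops$start2, loops$end2, loops$loop_id)
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(loops)
}

#' Read TSS records from BED6
#'
#' The BED name column holds the gene id; the TSS position is the BED
#' `start` coordinate.
#'
#' @param path File path.
#' @return Tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  fields <- read_table_checked(path, 6, "TSS BED")
  if (is.null(fields)) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          tss = integer(), strand = character()))
  }
  tibble::tibble(
    gene_id = chr_field(fields, 4),
    chrom = chr_field(fields, 1),
    tss = num_field(fields, 2, path, "TSS BED", integer = TRUE),
    strand = chr_field(fields, 6)
  )
}

#' Write TSS records as BED6
#'
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, optional `strand`).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_tss <- function(tss, path) {
  strand <- if ("strand" %in% names(tss)) tss$strand else "+"
  d <- data.frame(tss$chrom, tss$tss, tss$tss + 1L, tss$gene_id, 0L, strand)
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(tss)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample names, feature ids in the first
#' column and non-negative integer counts elsewhere; any negative or
#' non-integer entry is a hard error.
#'
#' @param path File path.
#' @return Tibble with a `feature` column and one column per sample.
#' @export
read_counts <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(d)[1] <- "feature"
  mat <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(is.na(mat)) || any(mat < 0) ||
      any(mat != round(mat))) {
    stop("counts must be non-negative integers: ", path, call. = FALSE)
  }
  d
}

#' Write a count matrix as TSV
#'
#' @param counts Count matrix or tibble (see [size_factors()]).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_counts <- function(counts, path) {
  mat <- count_input(counts)
  d <- tibble::as_tibble(mat, rownames = "feature")
  readr::write_tsv(d, path)
  invisible(counts)
}
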