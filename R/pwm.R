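#' Build a position weight matrix
#'
#' Converts a 4 x L count (or probability) matrix over A, C, G, T into
#' per-position probabilities with pseudocount smoothing:
#' `p[b, l] = (x[b, l] + pseudocount * bg[b]) / (sum(x[, l]) + pseudocount)`.
#'
#' @param x Numeric 4 x L matrix, rows in A, C, G, T order (rownames are
#'   honoured if present).
#' @param background Named background nucleotide frequencies summing
#'   to 1 (default uniform).
#' @param pseudocount Smoothing constant on the count scale (default 0.1).
#' @return An object of class `pwm`: list with `prob` (4 x L), `background`
#'   and `pseudocount`.
#' @export
pwm <- function(x, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.1) {
  bases <- c("A", "C", "G", "T")
  x <- as.matrix(x)
  if (nrow(x) != 4 || ncol(x) == 0) {
    stop("a PWM needs a 4-row, non-empty matrix", call. = FALSE)
  }
  if (!is.null(rownames(x))) x <- x[bases, , drop = FALSE]
  rownames(x) <- bases
  background <- background[bases]
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  prob <- sweep(x + pseudocount * background, 2,
                colSums(x) + pseudocount, "/")
  structure(list(prob = prob, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> length", ncol(x$prob), "| pseudocount", x$pseudocount, "\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' Read a JASPAR-style PFM text file
#'
#' Accepts the common JASPAR layouts: an optional `>` header line
#' followed by four rows of counts, either bare numbers (A, C, G, T
#' order) or prefixed `A [ ... ]` rows.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return A [pwm()] object.
#' @export
read_jaspar <- function(path,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                        pseudocount = 0.1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(>|#|$)", lines)]
  if (length(lines) < 4) stop("expected 4 count rows in ", path,
                              call. = FALSE)
  parse_row <- function(l) {
    l <- gsub("^\\s*[ACGTacgt]?\\s*\\[?", "", l)
    l <- gsub("\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }
  rows <- lapply(lines[1:4], parse_row)
  if (length(unique(lengths(rows))) != 1) {
    stop("ragged PFM rows in ", path, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, background = background, pseudocount = pseudocount)
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(seq, NULL),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

encode_seq <- function(sequence) {
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(toupper(sequence), NULL)[[1]]
  unname(codes[chars]) # N and anything else -> NA
}

#' Scan a sequence with a PWM
#'
#' Log-odds scan of both strands: each window of the motif length is
#' scored as `sum(log2(p[base, i] / bg[base]))`; windows containing a
#' non-ACGT character are skipped. Minus-strand hits are found by
#' scanning with the reverse-complemented matrix, so a reported hit at
#' `start` with strand `-` means the motif matches the reverse
#' complement of that window.
#'
#' @param sequence A single nucleotide string over A, C, G, T, N.
#' @param motif A [pwm()] object.
#' @param score_min Minimum reported log-odds score in bits.
#' @return Tibble with 1-based `start`, `strand` and `score`, sorted by
#'   position.
#' @export
pwm_scan <- function(sequence, motif, score_min = 0) {
  if (!inherits(motif, "pwm")) stop("motif must be a pwm object",
                                    call. = FALSE)
  L <- ncol(motif$prob)
  code <- encode_seq(sequence)
  n_win <- length(code) - L + 1
  if (n_win < 1) {
    stop("pwm length exceeds sequence length", call. = FALSE)
  }
  lods <- log2(motif$prob / motif$background)
  rc_lods <- lods[4:1, L:1, drop = FALSE] # complement rows, reverse cols
  score_strand <- function(mat) {
    s <- numeric(n_win)
    for (i in seq_len(L)) {
      s <- s + mat[cbind(code[i:(i + n_win - 1)], i)]
    }
    s # NA where the window touches a non-ACGT base
  }
  fwd <- score_strand(lods)
  rev_ <- score_strand(rc_lods)
  hits <- dplyr::bind_rows(
    tibble::tibble(start = which(!is.na(fwd) & fwd >= score_min),
                   strand = "+") |>
      dplyr::mutate(score = fwd[.data$start]),
    tibble::tibble(start = which(!is.na(rev_) & rev_ >= score_min),
                   strand = "-") |>
      dplyr::mutate(score = rev_[.data$start])
  )
  dplyr::arrange(hits, .data$start, .data$strand)
}

#' Flag peaks that contain a motif hit
#'
#' Sets `motif_hit = TRUE` for every peak whose sequence contains at
#' least one [pwm_scan()] hit at or above `score_min` on either strand.
#'
#' @param peaks Peak table.
#' @param sequences Named character vector of peak sequences, indexed by
#'   `peak_id`.
#' @param motif A [pwm()] object.
#' @param score_min Minimum log-odds score in bits.
#' @return The peak tibble with a logical `motif_hit` column.
#' @export
annotate_motif_hits <- function(peaks, sequences, motif, score_min = 0) {
  peaks <- as_peak_tbl(peaks)
  if (!all(peaks$peak_id %in% names(sequences))) {
    stop("sequences must be named by peak_id and cover every peak",
         call. = FALSE)
  }
  peaks$motif_hit <- vapply(peaks$peak_id, function(id) {
    nrow(pwm_scan(sequences[[id]], motif, score_min)) > 0
  }, logical(1), USE.NAMES = FALSE)
  peaks
}
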