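#' Simulation configuration
#'
#' One configuration object drives all three generators. Defaults plant
#' noiseless ground truth at desk scale; presets reproduce the study
#' conditions each end-to-end analysis assumes.
#'
#' Presets:
#' * `"switch"`: two-condition ChIP-style peak landscape with 240 lost,
#'   160 switch and 200 de novo sites and an exact integer motif
#'   planting (100 motif-positive low-condition sites, 73 of them on
#'   switch sites) so the motif-stratified overlap fractions are 0.73
#'   and 0.29 by construction.
#' * `"chain"`: loop universe planting the published connectivity chain
#'   5530 peaks, 1573 in anchors, 647 TSS-connected, 371 via conserved
#'   loops.
#' * `"de_null"`: 2000 NB features, two groups of 3, equal means (100),
#'   dispersion 0.1 — the type-I calibration scenario.
#' * `"de_power"`: as `"de_null"` with dispersion 0.05 and 200 features
#'   planted at an 8-fold change.
#'
#' @param seed Integer seed; the same seed gives identical output.
#' @param preset One of `"custom"`, `"switch"`, `"chain"`, `"de_null"`,
#'   `"de_power"`.
#' @param ... Named overrides of any configuration field (see the
#'   defaults in the function body; fields are validated).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       preset = c("custom", "switch", "chain", "de_null",
                                  "de_power"),
                       ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    # genome
    genome = c(chr1 = 50e6, chr2 = 50e6),
    # peak landscape
    n_lost = 240, n_switch = 160, n_denovo = 200, n_fail = 50,
    n_motif_switch = 73, n_motif_lost = 27,
    center_jitter_sd = 0, site_spacing = 5000, peak_halfwidth = 200,
    n_replicates_chip = 2,
    # counts
    n_genes = 2000, n_per_group = 3, nb_mean = 100, nb_dispersion = 0.1,
    n_de = 0, de_lfc = 0,
    # loop universe
    n_loops_shared = 150, n_loops_specific_high = 120,
    n_loops_specific_low = 60,
    anchor_jitter_sd = 0, loop_span = 200000, loop_stride = 280000,
    anchor_halfwidth = 5000, n_replicates_loops = 2,
    n_peaks_total = 600, n_peaks_in_anchors = 200,
    n_peaks_tss_connected = 110, n_via_conserved = 60,
    n_background_tss = 100
  )
  if (preset == "chain") {
    cfg$genome <- setNames(rep(100e6, 6), paste0("chr", 1:6))
    cfg$n_loops_shared <- 600
    cfg$n_loops_specific_high <- 1100
    cfg$n_loops_specific_low <- 200
    cfg$n_peaks_total <- 5530
    cfg$n_peaks_in_anchors <- 1573
    cfg$n_peaks_tss_connected <- 647
    cfg$n_via_conserved <- 371
    cfg$n_background_tss <- 300
  } else if (preset == "de_power") {
    cfg$nb_dispersion <- 0.05
    cfg$n_de <- 200
    cfg$de_lfc <- 3
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  counts <- unlist(cfg[c("n_lost", "n_switch", "n_denovo", "n_fail",
                         "n_genes", "n_per_group", "n_loops_shared",
                         "n_loops_specific_high", "n_loops_specific_low",
                         "n_peaks_total", "n_de")])
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$center_jitter_sd < 0 || cfg$anchor_jitter_sd < 0) {
    stop("jitter SDs must be >= 0", call. = FALSE)
  }
  if (cfg$n_motif_switch > cfg$n_switch || cfg$n_motif_lost > cfg$n_lost) {
    stop("planted motif counts exceed class sizes", call. = FALSE)
  }
  if (cfg$n_via_conserved > cfg$n_peaks_tss_connected ||
      cfg$n_peaks_tss_connected > cfg$n_peaks_in_anchors ||
      cfg$n_peaks_in_anchors > cfg$n_peaks_total) {
    stop("connectivity chain counts must be nested", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Lay out n positions spaced `spacing` apart across the genome,
# starting `margin` into each chromosome.
layout_positions <- function(genome, n, spacing, margin = 10000) {
  per_chrom <- floor((genome - 2 * margin) / spacing)
  if (sum(per_chrom) < n) {
    stop("site count exceeds genome capacity at the minimum spacing",
         call. = FALSE)
  }
  chroms <- rep(names(genome), per_chrom)
  offs <- unlist(lapply(per_chrom, function(k) margin + spacing * (seq_len(k) - 1)))
  tibble::tibble(chrom = chroms[seq_len(n)], pos = offs[seq_len(n)])
}

jitter_pos <- function(pos, sd, lo = 0, hi = Inf) {
  if (sd == 0) return(pos)
  pmin(pmax(pos + round(rnorm(length(pos), 0, sd)), lo), hi)
}

#' Simulate a two-condition binding-site landscape
#'
#' Plants lost, switch and de novo sites on the configured genome at a
#' fixed spacing, emits peaks for each condition with Gaussian center
#' jitter, per-replicate fold enrichments drawn above the filtering
#' thresholds for planted-pass sites, and q-values that make the
#' reproducibility filters unambiguous (passing peaks in (0, 1e-5),
#' failing peaks in (1e-3, 1)). Motif flags are planted with exact
#' integer counts per class.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `low_peaks`, `high_peaks` (both including
#'   the planted filter-failing peaks) and `truth` (one row per planted
#'   site: `site_id`, `class`, `chrom`, `pos`, peak ids per condition,
#'   `motif_hit`, `passes_filters`).
#' @export
simulate_peak_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sites <- config$n_lost + config$n_switch + config$n_denovo +
    2 * config$n_fail
  sites <- layout_positions(config$genome, n_sites, config$site_spacing)
  classes <- c(rep("lost", config$n_lost),
               rep("switch", config$n_switch),
               rep("denovo", config$n_denovo),
               rep("fail_low", config$n_fail),
               rep("fail_high", config$n_fail))
  sites$class <- sample(classes) # shuffle class layout along the genome
  sites$site_id <- sprintf("site_%05d", seq_len(n_sites))
  # exact integer motif planting on low-condition pass sites
  sites$motif_hit <- FALSE
  sw_idx <- which(sites$class == "switch")
  lost_idx <- which(sites$class == "lost")
  sites$motif_hit[sw_idx[seq_len(config$n_motif_switch)]] <- TRUE
  sites$motif_hit[lost_idx[seq_len(config$n_motif_lost)]] <- TRUE

  hw <- config$peak_halfwidth
  nrep <- config$n_replicates_chip
  make_peaks <- function(idx, prefix, passing) {
    n <- length(idx)
    center <- jitter_pos(sites$pos[idx], config$center_jitter_sd, lo = hw)
    p <- tibble::tibble(
      peak_id = sprintf("%s_%05d", prefix, seq_len(n)),
      chrom = sites$chrom[idx],
      start = as.integer(center - hw),
      end = as.integer(center + hw + 1),
      center = as.integer(center),
      condition = prefix,
      motif_hit = sites$motif_hit[idx],
      site_id = sites$site_id[idx]
    )
    p$q_value <- ifelse(passing,
                        runif(n, 0, 1e-5),
                        runif(n, 1e-3, 1))
    for (k in seq_len(nrep)) {
      p[[paste0("fe_", k)]] <- ifelse(passing,
                                      21 + rgamma(n, shape = 2, scale = 12),
                                      runif(n, 0, 8))
    }
    p
  }
  low_idx <- c(which(sites$class %in% c("lost", "switch")),
               which(sites$class == "fail_low"))
  low_pass <- sites$class[low_idx] != "fail_low"
  high_idx <- c(which(sites$class %in% c("switch", "denovo")),
                which(sites$class == "fail_high"))
  high_pass <- sites$class[high_idx] != "fail_high"
  low <- make_peaks(low_idx, "low", low_pass)
  high <- make_peaks(high_idx, "high", high_pass)
  truth <- sites
  truth$low_peak_id <- low$peak_id[match(truth$site_id, low$site_id)]
  truth$high_peak_id <- high$peak_id[match(truth$site_id, high$site_id)]
  truth$passes_filters <- !truth$class %in% c("fail_low", "fail_high")
  list(low_peaks = low, high_peaks = high, truth = truth)
}

#' Simulate an NB count matrix with known fold changes
#'
#' Counts follow `NB(mean = base * sf_j * 2^(lfc_i * group),
#' size = 1 / dispersion)` with per-sample size factors drawn
#' log-uniformly in `[0.5, 2]`. The first `n_de` features carry the
#' planted log2 fold change `de_lfc` (group B over A); all others are
#' null.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (tibble, feature column + one column per
#'   sample), `design` (`sample`, `group` with groups `low` / `high`),
#'   `lengths` (tibble `feature`, `length` for TPM), `size_factors`
#'   (true values) and `truth` (`feature`, `true_lfc`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_mean <= 0) stop("nb_mean must be > 0", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- config$n_genes
  npg <- config$n_per_group
  feats <- sprintf("gene_%05d", seq_len(n))
  samples <- c(sprintf("low_%d", seq_len(npg)),
               sprintf("high_%d", seq_len(npg)))
  design <- tibble::tibble(sample = samples,
                           group = rep(c("low", "high"), each = npg))
  sf <- exp(runif(2 * npg, log(0.5), log(2)))
  lfc <- c(rep(config$de_lfc, config$n_de), rep(0, n - config$n_de))
  mu <- outer(rep(config$nb_mean, n), sf) *
    2^(outer(lfc, as.numeric(design$group == "high")))
  counts <- matrix(rnbinom(n * 2 * npg, mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = list(feats, samples))
  lengths <- tibble::tibble(feature = feats,
                            length = round(runif(n, 500, 5000)))
  list(
    counts = tibble::as_tibble(counts, rownames = "feature"),
    design = design,
    lengths = lengths,
    size_factors = setNames(sf, samples),
    truth = tibble::tibble(feature = feats, true_lfc = lfc)
  )
}

#' Simulate a loop universe with planted peak-TSS connectivity
#'
#' Lays out non-overlapping loop blocks (anchor pair plus flanking gap)
#' across the genome, emits shared loops in both conditions and
#' condition-specific loops in one, with per-replicate Gaussian anchor
#' jitter, then plants the connectivity chain: a configured number of
#' peaks placed 2 kb from an anchor center (inside the 5 kb rule),
#' TSSs placed 8 kb from the partner anchor center (inside the 15 kb
#' rule) for the TSS-connected subset, the conserved/specific split
#' taken from shared vs high-specific host loops, and the remaining
#' peaks placed in inter-block gaps well away from every anchor.
#'
#' @param config A [sim_config()].
#' @return List with `loops` (all conditions and replicates; replicate 1
#'   is the condition-level call set), `peaks` (high-condition peak
#'   table), `tss` (planted plus background TSS records) and `truth`
#'   (planted loop table with classes, per-peak roles, and the intended
#'   `connectivity` count table).
#' @export
simulate_loop_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_loops <- config$n_loops_shared + config$n_loops_specific_high +
    config$n_loops_specific_low
  blocks <- layout_positions(config$genome, n_loops, config$loop_stride,
                             margin = 20000)
  gap <- config$loop_stride - config$loop_span - 2 * config$anchor_halfwidth
  if (gap <= 0) stop("loop_stride must exceed loop_span plus anchors",
                     call. = FALSE)
  if (2 * config$anchor_jitter_sd > gap / 2) {
    warning("anchor jitter is large relative to anchor spacing; ",
            "matching may be ambiguous", call. = FALSE)
  }
  classes <- sample(c(rep("shared", config$n_loops_shared),
                      rep("specific_high", config$n_loops_specific_high),
                      rep("specific_low", config$n_loops_specific_low)))
  truth_loops <- tibble::tibble(
    true_id = sprintf("true_%05d", seq_len(n_loops)),
    chrom = blocks$chrom,
    anchor1 = blocks$pos,
    anchor2 = blocks$pos + config$loop_span,
    loop_class = classes
  )
  ahw <- config$anchor_halfwidth
  emit <- function(cond, rep_idx) {
    keep <- truth_loops$loop_class %in%
      c("shared", paste0("specific_", cond))
    d <- truth_loops[keep, ]
    c1 <- jitter_pos(d$anchor1, config$anchor_jitter_sd, lo = ahw)
    c2 <- jitter_pos(d$anchor2, config$anchor_jitter_sd, lo = ahw)
    tibble::tibble(
      loop_id = sprintf("%s_r%d_%05d", cond, rep_idx, seq_len(nrow(d))),
      chrom1 = d$chrom, start1 = as.integer(c1 - ahw),
      end1 = as.integer(c1 + ahw),
      chrom2 = d$chrom, start2 = as.integer(c2 - ahw),
      end2 = as.integer(c2 + ahw),
      condition = cond, replicate = rep_idx,
      true_id = d$true_id
    )
  }
  loops <- dplyr::bind_rows(lapply(c("low", "high"), function(cond) {
    dplyr::bind_rows(lapply(seq_len(config$n_replicates_loops),
                            function(r) emit(cond, r)))
  }))

  # --- plant the peak chain on high-condition loops -----------------
  n_conn <- config$n_peaks_tss_connected
  n_cons <- config$n_via_conserved
  n_spec <- n_conn - n_cons
  n_anch_only <- config$n_peaks_in_anchors - n_conn
  shared_ids <- truth_loops$true_id[truth_loops$loop_class == "shared"]
  spec_ids <- truth_loops$true_id[truth_loops$loop_class == "specific_high"]
  if (length(shared_ids) < n_cons || length(spec_ids) < n_spec) {
    stop("not enough loops of each class to host the planted chain",
         call. = FALSE)
  }
  host_conn <- c(shared_ids[seq_len(n_cons)],
                 spec_ids[seq_len(n_spec)])
  remaining <- setdiff(c(shared_ids, spec_ids), host_conn)
  if (length(remaining) < n_anch_only) {
    stop("not enough loops to host anchored-but-unconnected peaks",
         call. = FALSE)
  }
  host_anch <- remaining[seq_len(n_anch_only)]

  tl <- truth_loops
  anchored_hosts <- c(host_conn, host_anch)
  hi <- match(anchored_hosts, tl$true_id)
  anchored_peaks <- tibble::tibble(
    chrom = tl$chrom[hi],
    center = tl$anchor1[hi] + 2000L,
    role = c(rep("tss_connected", n_conn), rep("anchor_only", n_anch_only)),
    host_loop = anchored_hosts
  )
  n_free <- config$n_peaks_total - config$n_peaks_in_anchors
  # free peaks go into inter-block gaps, >= 14 kb from any anchor center
  gap_slots <- min(5, floor(gap / 10000))
  free_blocks <- rep(seq_len(n_loops), each = gap_slots)
  free_offsets <- rep(10000 * (seq_len(gap_slots) - 1), times = n_loops)
  if (length(free_blocks) < n_free) {
    stop("not enough gap space for unanchored peaks", call. = FALSE)
  }
  sel <- seq_len(n_free)
  free_peaks <- tibble::tibble(
    chrom = tl$chrom[free_blocks[sel]],
    center = as.integer(tl$anchor2[free_blocks[sel]] + ahw + 9000 +
                          free_offsets[sel]),
    role = "unanchored",
    host_loop = NA_character_
  )
  peaks <- dplyr::bind_rows(anchored_peaks, free_peaks)
  peaks <- tibble::tibble(
    peak_id = sprintf("bpeak_%05d", seq_len(nrow(peaks))),
    chrom = peaks$chrom,
    start = as.integer(peaks$center - 200L),
    end = as.integer(peaks$center + 201L),
    center = as.integer(peaks$center),
    condition = "high",
    role = peaks$role,
    host_loop = peaks$host_loop
  )

  ci <- match(host_conn, tl$true_id)
  tss_planted <- tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(n_conn)),
    chrom = tl$chrom[ci],
    tss = as.integer(tl$anchor2[ci] + 8000L),
    strand = rep_len(c("+", "-"), n_conn),
    planted = TRUE
  )
  n_bg <- config$n_background_tss
  bg_blocks <- seq_len(min(n_bg, n_loops))
  tss_bg <- tibble::tibble(
    gene_id = sprintf("bg_gene_%05d", seq_along(bg_blocks)),
    chrom = tl$chrom[bg_blocks],
    # mid-gap, > 15 kb from the flanking anchor centers
    tss = as.integer(tl$anchor2[bg_blocks] + 40500L),
    strand = "+",
    planted = FALSE
  )
  tss <- dplyr::bind_rows(tss_planted, tss_bg)

  connectivity <- tibble::tibble(
    n_peaks_total = config$n_peaks_total,
    n_peaks_in_anchors = config$n_peaks_in_anchors,
    n_peaks_tss_connected = n_conn,
    n_via_conserved_loops = n_cons,
    n_via_specific_loops = n_spec
  )
  list(loops = loops, peaks = peaks, tss = tss,
       truth = list(loops = truth_loops, peaks = peaks[, c("peak_id", "role",
                                                           "host_loop")],
                    connectivity = connectivity))
}
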