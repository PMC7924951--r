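# Independent all-pairs brute-force oracles used to cross-check the
# package's matching/merging/connectivity implementations, plus small
# random-instance generators. The oracles work on full distance
# matrices with repeated global argmin extraction, independently of the
# join-based implementations in R/.

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                       width = 200) {
  center <- sample.int(max_pos, n, replace = TRUE) + width
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = center - width %/% 2,
    end = center + width %/% 2 + 1,
    center = center
  )
}

rand_loops <- function(n, chroms = c("chr1", "chr2"), max_pos = 5e7,
                       span_min = 5e4, span_max = 5e5, anchor_hw = 5000) {
  a1 <- sample.int(max_pos, n, replace = TRUE) + anchor_hw
  a2 <- a1 + sample(span_min:span_max, n, replace = TRUE)
  tibble::tibble(
    chrom1 = sample(chroms, n, replace = TRUE),
    start1 = a1 - anchor_hw, end1 = a1 + anchor_hw,
    chrom2 = character(n), start2 = a2 - anchor_hw, end2 = a2 + anchor_hw
  ) |> dplyr::mutate(chrom2 = chrom1)
}

rand_tss <- function(n, chroms = c("chr1", "chr2"), max_pos = 5e7) {
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = sample.int(max_pos, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# distance matrix between the centers of two peak tables (Inf across
# chromosomes)
center_dist_matrix <- function(a, b) {
  d <- abs(outer(as.numeric(a$center), as.numeric(b$center), "-"))
  same <- outer(a$chrom, b$chrom, "==")
  d[!same] <- Inf
  d
}

# one-to-one matching by repeated global argmin with the deterministic
# tie-break (distance, min start, max start, min center)
oracle_match_sets <- function(a, b, threshold) {
  a <- switchloop::as_peak_tbl(a)
  b <- switchloop::as_peak_tbl(b)
  d <- center_dist_matrix(a, b)
  cand <- which(d <= threshold, arr.ind = TRUE)
  res <- NULL
  while (nrow(cand) > 0) {
    i <- cand[, 1]
    j <- cand[, 2]
    key <- order(d[cand],
                 pmin(a$start[i], b$start[j]),
                 pmax(a$start[i], b$start[j]),
                 pmin(a$center[i], b$center[j]))[1]
    pick <- cand[key, , drop = FALSE]
    res <- rbind(res, pick)
    cand <- cand[cand[, 1] != pick[1] & cand[, 2] != pick[2], ,
                 drop = FALSE]
  }
  if (is.null(res)) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  }
  out <- tibble::tibble(idx_a = as.integer(res[, 1]),
                        idx_b = as.integer(res[, 2]))
  dplyr::arrange(out, idx_a)
}

# greedy chained merging of a sorted numeric center vector
oracle_merge_centers <- function(centers, threshold) {
  centers <- sort(centers)
  out <- numeric(0)
  cur <- centers[1]
  for (x in centers[-1]) {
    if (x - cur <= threshold) cur <- floor((cur + x) / 2)
    else {
      out <- c(out, cur)
      cur <- x
    }
  }
  c(out, cur)
}

loop_dists <- function(l1, l2, i, j) {
  if (l1$chrom1[i] != l2$chrom1[j] || l1$chrom2[i] != l2$chrom2[j]) {
    return(c(Inf, Inf))
  }
  c(abs(l1$center1[i] - l2$center1[j]), abs(l1$center2[i] - l2$center2[j]))
}

# replicated = at least one partner with both anchors within tol
oracle_reconcile <- function(rep1, rep2, tol) {
  rep1 <- switchloop::as_loop_tbl(rep1)
  rep2 <- switchloop::as_loop_tbl(rep2)
  ok <- logical(nrow(rep1))
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      dd <- loop_dists(rep1, rep2, i, j)
      if (dd[1] <= tol && dd[2] <= tol) {
        ok[i] <- TRUE
        break
      }
    }
  }
  which(ok)
}

oracle_assign <- function(peaks, loops, tol) {
  peaks <- switchloop::as_peak_tbl(peaks)
  loops <- switchloop::as_loop_tbl(loops)
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(loops))) {
      for (side in 1:2) {
        ch <- loops[[paste0("chrom", side)]][j]
        ce <- loops[[paste0("center", side)]][j]
        if (peaks$chrom[i] == ch && abs(peaks$center[i] - ce) <= tol) {
          res[[length(res) + 1]] <- tibble::tibble(
            peak_id = peaks$peak_id[i], loop_id = loops$loop_id[j],
            side = side, distance = abs(peaks$center[i] - ce))
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(peak_id = character(), loop_id = character(),
                          side = integer(), distance = numeric()))
  }
  dplyr::arrange(out, peak_id, loop_id, side)
}

oracle_connect <- function(assignments, loops, tss, tol) {
  loops <- switchloop::as_loop_tbl(loops)
  res <- list()
  for (k in seq_len(nrow(assignments))) {
    other <- 3L - assignments$side[k]
    j <- match(assignments$loop_id[k], loops$loop_id)
    ch <- loops[[paste0("chrom", other)]][j]
    ce <- loops[[paste0("center", other)]][j]
    for (t in seq_len(nrow(tss))) {
      if (tss$chrom[t] == ch && abs(tss$tss[t] - ce) <= tol) {
        res[[length(res) + 1]] <- tibble::tibble(
          peak_id = assignments$peak_id[k],
          loop_id = assignments$loop_id[k],
          side = assignments$side[k],
          gene_id = tss$gene_id[t],
          tss_distance = abs(tss$tss[t] - ce))
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(peak_id = character(), loop_id = character(),
                          side = integer(), gene_id = character(),
                          tss_distance = numeric()))
  }
  dplyr::arrange(out, peak_id, loop_id, gene_id)
}

# fraction of planted sites whose class is recovered by classify_sites
# run on the filtered peak sets
class_recovery <- function(landscape, threshold = 150) {
  low <- suppressMessages(filter_chip_peaks(landscape$low_peaks))
  high <- suppressMessages(filter_chip_peaks(landscape$high_peaks))
  cls <- classify_sites(low, high, threshold)
  truth <- landscape$truth[landscape$truth$passes_filters, ]
  lost_ok <- truth$low_peak_id[truth$class == "lost"] %in%
    cls$lost$peak_id
  dn_ok <- truth$high_peak_id[truth$class == "denovo"] %in%
    cls$denovo$peak_id
  key <- paste(cls$switch$peak_a, cls$switch$peak_b)
  sw <- truth[truth$class == "switch", ]
  sw_ok <- paste(sw$low_peak_id, sw$high_peak_id) %in% key
  mean(c(lost_ok, dn_ok, sw_ok))
}
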