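mk_loop <- function(c1, c2, chrom = "chr1", hw = 5000, id = NULL) {
  d <- data.frame(chrom1 = chrom, start1 = c1 - hw, end1 = c1 + hw,
                  chrom2 = chrom, start2 = c2 - hw, end2 = c2 + hw)
  if (!is.null(id)) d$loop_id <- id
  d
}

test_that("replicate reconciliation applies the 10 kb rule per anchor", {
  l1 <- mk_loop(15000, 115000)
  # both anchors shifted +5 kb: replicated
  expect_equal(nrow(suppressMessages(
    reconcile_replicate_loops(l1, mk_loop(20000, 120000)))), 1)
  # one anchor off by 15 kb: a single failing anchor suffices
  expect_equal(nrow(suppressMessages(
    reconcile_replicate_loops(l1, mk_loop(20000, 130000)))), 0)
  # identity replicates everything
  set.seed(111)
  many <- rand_loops(40)
  rec <- suppressMessages(reconcile_replicate_loops(many, many))
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$anchor1_distance == 0))
})

test_that("condition comparison partitions and respects the boundary", {
  a <- mk_loop(50000, 250000)
  jitter9 <- mk_loop(59000, 259000)
  jitter11 <- mk_loop(61000, 261000)
  cmp9 <- suppressMessages(compare_condition_loops(a, jitter9))
  expect_equal(nrow(cmp9$shared), 1)
  cmp11 <- suppressMessages(compare_condition_loops(a, jitter11))
  expect_equal(nrow(cmp11$shared), 0)
  expect_equal(nrow(cmp11$specific_1), 1)
  expect_equal(nrow(cmp11$specific_2), 1)

  set.seed(222)
  c1 <- rand_loops(60)
  c2 <- rand_loops(60)
  cmp <- suppressMessages(compare_condition_loops(c1, c2))
  g <- glance(cmp)
  expect_equal(g$n_shared + g$n_specific_1, 60)
  expect_equal(g$n_shared + g$n_specific_2, 60)
  # symmetry of the matched pair set under condition swap (ids are
  # regenerated per call, so compare the numeric suffixes)
  idx <- function(id) sub(".*_", "", id)
  swap <- suppressMessages(compare_condition_loops(c2, c1))
  expect_setequal(paste(idx(cmp$shared$loop_id), idx(cmp$shared$partner_id)),
                  paste(idx(swap$shared$partner_id), idx(swap$shared$loop_id)))
})

test_that("anchor assignment and TSS connection respect their tolerances", {
  loop <- mk_loop(15000, 215000, id = "L1")
  near <- data.frame(chrom = "chr1", start = 11900, end = 12100)  # 3 kb
  far <- data.frame(chrom = "chr1", start = 20900, end = 21100)   # 6 kb
  expect_equal(nrow(assign_peaks_to_anchors(near, loop)), 1)
  expect_equal(nrow(assign_peaks_to_anchors(far, loop)), 0)
  expect_equal(nrow(assign_peaks_to_anchors(near, loop[0, ])), 0)

  asn <- assign_peaks_to_anchors(near, loop)
  tss_near <- data.frame(gene_id = "gA", chrom = "chr1", tss = 229000,
                         strand = "+") # 14 kb from anchor2
  tss_far <- data.frame(gene_id = "gB", chrom = "chr1", tss = 230500,
                        strand = "+") # 15.5 kb
  tss_same_side <- data.frame(gene_id = "gC", chrom = "chr1", tss = 16000,
                              strand = "+") # near anchor1, same side as peak
  expect_equal(connect_peaks_to_tss(asn, loop, tss_near)$gene_id, "gA")
  expect_equal(nrow(connect_peaks_to_tss(asn, loop, tss_far)), 0)
  expect_equal(nrow(connect_peaks_to_tss(asn, loop, tss_same_side)), 0)
})

test_that("loop chain operations agree with all-pairs brute-force oracles", {
  set.seed(333)
  for (rep in 1:15) {
    l1 <- rand_loops(sample(10:50, 1))
    l2 <- rand_loops(sample(10:50, 1))
    rec <- suppressMessages(reconcile_replicate_loops(l1, l2, 10000))
    expect_equal(match(rec$loop_id, as_loop_tbl(l1, "rep1")$loop_id),
                 oracle_reconcile(l1, l2, 10000))

    peaks <- rand_peaks(sample(20:80, 1), max_pos = 5e7)
    loops <- as_loop_tbl(rand_loops(sample(10:40, 1)))
    asn <- assign_peaks_to_anchors(peaks, loops, 5000)
    ora <- oracle_assign(peaks, loops, 5000)
    expect_equal(asn$peak_id, ora$peak_id)
    expect_equal(asn$loop_id, ora$loop_id)
    expect_equal(asn$side, as.integer(ora$side))

    tss <- rand_tss(sample(20:60, 1))
    conn <- connect_peaks_to_tss(asn, loops, tss, 15000)
    orc <- oracle_connect(asn, loops, tss, 15000)
    expect_equal(conn$peak_id, orc$peak_id)
    expect_equal(conn$gene_id, orc$gene_id)
    expect_equal(conn$tss_distance, orc$tss_distance)
  }
})

test_that("enlarging tolerances never shrinks the connectivity chain", {
  set.seed(444)
  u <- simulate_loop_universe(sim_config(seed = 444, anchor_jitter_sd = 1000))
  high <- dplyr::filter(u$loops, condition == "high", replicate == 1)
  low <- dplyr::filter(u$loops, condition == "low", replicate == 1)
  prev_anch <- -1
  prev_tss <- -1
  for (scale in c(0.5, 1, 2)) {
    cmp <- suppressMessages(compare_condition_loops(low, high, 10000 * scale))
    rep <- connectivity_summary(u$peaks, cmp$shared_2, cmp$specific_2,
                                u$tss, peak_tol = 5000 * scale,
                                tss_tol = 15000 * scale)
    expect_gte(rep$n_peaks_in_anchors, prev_anch)
    expect_gte(rep$n_peaks_tss_connected, prev_tss)
    prev_anch <- rep$n_peaks_in_anchors
    prev_tss <- rep$n_peaks_tss_connected
  }
})

test_that("connectivity summary reproduces the published chain identities", {
  # the printed chain: 5530 sites -> 1573 in anchors -> 647 at TSS ->
  # 371 via conserved loops, i.e. 28% / 41% / 57%
  u <- simulate_loop_universe(sim_config(seed = 5, preset = "chain"))
  low <- dplyr::filter(u$loops, condition == "low", replicate == 1)
  high <- dplyr::filter(u$loops, condition == "high", replicate == 1)
  res <- suppressMessages(run_loop_pipeline(u$peaks, low, high, u$tss))
  g <- glance(res$report)
  expect_equal(g$n_peaks_total, 5530)
  expect_equal(g$n_peaks_in_anchors, 1573)
  expect_equal(g$n_peaks_tss_connected, 647)
  expect_equal(g$n_via_conserved_loops, 371)
  expect_equal(g$pct_in_anchors, 28)
  expect_equal(g$pct_tss_connected, 41)
  expect_equal(g$pct_via_conserved, 57)

  # degenerate input: no loops at all
  empty <- connectivity_summary(u$peaks, high[0, ], high[0, ], u$tss)
  expect_equal(empty$n_peaks_in_anchors, 0)
  expect_equal(empty$pct_in_anchors, 0)
})
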