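test_that("RPKM conversion follows the formula and its scaling laws", {
  layout <- toy_layout(1, 1e5)
  tr <- signal_track(list(chr1 = c(10, 0, rep(0, 998))), 100, layout,
                     units = "count")
  expect_equal(counts_to_rpkm(tr, 1e6)$values$chr1[1], 100)
  expect_equal(counts_to_rpkm(tr, 1e6)$values$chr1[2], 0)
  expect_equal(counts_to_rpkm(tr, 2e6)$values$chr1[1], 50)
  # linear in counts, inverse-linear in library total
  tr2 <- signal_track(list(chr1 = c(30, 0, rep(0, 998))), 100, layout,
                      units = "count")
  expect_equal(counts_to_rpkm(tr2, 1e6)$values$chr1[1],
               3 * counts_to_rpkm(tr, 1e6)$values$chr1[1])
  expect_error(counts_to_rpkm(tr, 0), "library_total")
})

test_that("input subtraction retains negative values and is exact", {
  layout <- toy_layout(1, 1e5)
  mk <- function(v) signal_track(list(chr1 = c(v, rep(0, 999))), 100, layout,
                                 units = "RPKM")
  expect_equal(input_subtract(mk(100), mk(40))$values$chr1[1], 60)
  expect_equal(input_subtract(mk(0), mk(5))$values$chr1[1], -5)
  self <- input_subtract(mk(7), mk(7))
  expect_true(all(self$values$chr1 == 0))
  bad <- signal_track(list(chr1 = rep(0, 2000)), 50, layout, units = "RPKM")
  expect_error(input_subtract(mk(1), bad), "bin sizes")
})

test_that("window aggregation matches a direct loop computation", {
  layout <- toy_layout(1, 1e5)
  # constant track: mean mode is the identity on the value
  const <- signal_track(list(chr1 = rep(3.5, 1000)), 100, layout,
                        units = "RPKM")
  agg <- aggregate_to_windows(const, 5000, "mean")
  expect_true(all(agg$values$chr1 == 3.5))
  ones <- signal_track(list(chr1 = rep(1, 1000)), 100, layout, units = "RPKM")
  expect_true(all(aggregate_to_windows(ones, 5000, "sum")$values$chr1 == 50))

  set.seed(21)
  v <- rnorm(1000)
  tr <- signal_track(list(chr1 = v), 100, layout, units = "input_RPKM")
  got <- aggregate_to_windows(tr, 5000, "mean")$values$chr1
  naive <- vapply(seq_len(20), function(w) mean(v[((w - 1) * 50 + 1):(w * 50)]),
                  numeric(1))
  expect_equal(got, naive, tolerance = 1e-12)
  expect_error(aggregate_to_windows(tr, 5150), "multiple")
})

test_that("co-occupancy windows require both marks across any sample", {
  layout <- toy_layout(1, 1e5)
  a1 <- gr_feats(layout, "chr1", 1000, 1400)       # window 0 (mark A, s1)
  a2 <- gr_feats(layout, "chr1", 52000, 52400)     # window 10 (mark A, s2)
  b1 <- gr_feats(layout, "chr1", c(2000, 52400), c(2400, 52800))  # windows 0, 10
  tab <- cooccupancy_windows(list(a1, a2), list(b1), 5000, layout)
  expect_equal(tab$start, c(0, 50000))
  expect_true(tab$hasA_1[1] && !tab$hasA_2[1])
  expect_true(tab$hasA_2[2] && tab$hasB_1[2])

  # windows with only one mark are excluded
  only_a <- cooccupancy_windows(list(a1), list(gr_feats(layout, "chr1", 90000, 90400)),
                                5000, layout)
  expect_equal(nrow(only_a), 0)
  # empty peak set for one mark -> empty table; empty sample list -> error
  empty <- gr_feats(layout, character(), numeric(), numeric())
  expect_equal(nrow(cooccupancy_windows(list(a1), list(empty), 5000, layout)), 0)
  expect_error(cooccupancy_windows(list(), list(b1), 5000, layout), "peak set")

  # monotonicity: adding peaks never removes a window
  more_b <- c(b1, gr_feats(layout, "chr1", 52400, 52800))
  tab2 <- cooccupancy_windows(list(a1, a2), list(more_b), 5000, layout)
  expect_true(all(paste(tab$chrom, tab$start) %in% paste(tab2$chrom, tab2$start)))
})

test_that("exclusivity summary equals direct Pearson and threshold arithmetic", {
  tab <- data.table::data.table(sigA = c(5, 4, 3, 2, 1, 0),
                                sigB = c(0, 1, 2, 3, 4, 5))
  s <- exclusivity_summary(tab, "sigA", "sigB", high_quantile = 0.5)
  expect_equal(s$r, -1)
  expect_equal(s$double_high_fraction, 0)

  tab2 <- data.table::data.table(sigA = 1:6, sigB = 1:6)
  s2 <- exclusivity_summary(tab2, "sigA", "sigB", high_quantile = 0.5)
  expect_equal(s2$r, 1)
  expect_equal(s2$double_high_fraction, mean(1:6 > median(1:6)))

  set.seed(9)
  tab3 <- data.table::data.table(sigA = rnorm(6), sigB = rnorm(6))
  s3 <- exclusivity_summary(tab3, "sigA", "sigB", high_quantile = 0.9)
  expect_equal(s3$r, cor(tab3$sigA, tab3$sigB))
  qa <- quantile(tab3$sigA, 0.9, names = FALSE)
  qb <- quantile(tab3$sigB, 0.9, names = FALSE)
  expect_equal(s3$double_high_fraction, mean(tab3$sigA > qa & tab3$sigB > qb))

  const <- data.table::data.table(sigA = rep(1, 5), sigB = rnorm(5))
  expect_warning(sc <- exclusivity_summary(const, "sigA", "sigB"), "constant")
  expect_true(is.na(sc$r))
})

test_that("profiles around anchors average columnwise with edge padding", {
  layout <- toy_layout(1, 1e5)
  v <- rep(0, 1000); v[501] <- 9  # one nonzero bin
  tr <- signal_track(list(chr1 = v), 100, layout, units = "normalized")
  # anchor midpoint in bin 501 -> delta at offset 0
  anch <- gr_feats(layout, "chr1", 50000, 50100)
  pr <- profile_around(tr, anch, 500)
  expect_equal(which.max(pr$mean_curve), 6)  # offset 0 of -5..5
  expect_equal(pr$offsets, seq(-500, 500, by = 100))

  const <- signal_track(list(chr1 = rep(2, 1000)), 100, layout,
                        units = "normalized")
  expect_true(all(profile_around(const, anch, 500)$mean_curve == 2))

  # two anchors, hand-built track: columnwise means equal manual averages
  v2 <- seq_len(1000) / 10
  tr2 <- signal_track(list(chr1 = v2), 100, layout, units = "normalized")
  anch2 <- gr_feats(layout, "chr1", c(10000, 70000), c(10100, 70100))
  pr2 <- profile_around(tr2, anch2, 300)
  manual <- (v2[98:104] + v2[698:704]) / 2
  expect_equal(pr2$mean_curve, manual)

  # anchor at the chromosome edge: missing positions excluded positionwise
  edge <- gr_feats(layout, "chr1", 0, 100)
  pre <- profile_around(tr2, edge, 300)
  expect_true(all(is.na(pre$matrix[1, 1:3])))
  expect_equal(pre$mean_curve[4:7], v2[1:4])
})

test_that("methylation windows pool counts and mask low coverage", {
  layout <- toy_layout(1, 1e4)
  calls <- data.frame(chrom = "chr1",
                      pos = c(10, 60, 150, 310),
                      coverage = c(6, 6, 4, 8),
                      methylated = c(3, 6, 2, 8))
  tr <- methylation_windows(calls, layout, window_size = 100, min_reads = 5)
  expect_equal(tr$values$chr1[1], 9 / 12)     # pooled, not mean of ratios
  expect_true(is.na(tr$values$chr1[2]))       # coverage 4 < 5 -> masked
  expect_equal(tr$values$chr1[4], 1)          # fully methylated
  expect_true(is.na(tr$values$chr1[5]))       # no sites -> masked
  bad <- calls; bad$methylated[1] <- 10
  expect_error(methylation_windows(bad, layout), "exceeds")
})

test_that("row clustering is seeded, deterministic and recovers planted blobs", {
  set.seed(2)
  blob1 <- matrix(rnorm(50 * 4, mean = 0), ncol = 4)
  blob2 <- matrix(rnorm(40 * 4, mean = 8), ncol = 4)
  mat <- rbind(blob1, blob2)
  cl <- cluster_rows(mat, k = 2, seed = 99)
  truth <- rep(1:2, c(50, 40))
  agreement <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agreement, 1)
  cl2 <- cluster_rows(mat, k = 2, seed = 99)
  expect_identical(cl$labels, cl2$labels)

  one <- cluster_rows(mat, k = 1, seed = 1)
  expect_true(all(one$labels == 1))
  expect_error(cluster_rows(mat, k = 1000, seed = 1), "exceeds")
  expect_error(cluster_rows(matrix(c(1, NA, 2, 3), 2), k = 1, seed = 1), "finite")
})

test_that("count_in_features sums the covered bins exactly", {
  layout <- toy_layout(1, 1e4)
  set.seed(14)
  v <- rpois(100, 3)
  tr <- signal_track(list(chr1 = as.numeric(v)), 100, layout, units = "count")
  feats <- gr_feats(layout, rep("chr1", 3), c(0, 250, 9900), c(500, 300, 10000))
  got <- count_in_features(tr, feats)
  expect_equal(got, c(sum(v[1:5]), v[3], v[100]))
})
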