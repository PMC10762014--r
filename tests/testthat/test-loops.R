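mk_pairs <- function(chrom, b1, b2, res = 25000, name = NULL) {
  data.table::data.table(chrom = chrom, start1 = b1 * res, end1 = (b1 + 1) * res,
                         start2 = b2 * res, end2 = (b2 + 1) * res,
                         resolution = res,
                         name = if (is.null(name)) sprintf("L%d", seq_along(b1)) else name)
}

test_that("exact-anchor loop merging is a provenance-tracking union", {
  L1 <- mk_pairs("chr1", 10, 20); L2 <- mk_pairs("chr1", 30, 44)
  L3 <- mk_pairs("chr1", 50, 61)
  s1 <- rbind(L1, L2); s2 <- rbind(L1, L3)
  m <- merge_loops(list(WT = s1, KO = s2))
  expect_equal(nrow(m), 3)
  expect_equal(m$called_in[m$start1 == 10 * 25000], "KO,WT")
  # idempotence and identity
  expect_equal(nrow(merge_loops(list(a = s1, b = s1))), nrow(s1))
  expect_equal(nrow(merge_loops(list(a = s1[0, ], b = s1))), nrow(s1))
  # associativity (by key set)
  keyset <- function(x) sort(paste(x$chrom, x$start1, x$start2))
  m12_3 <- merge_loops(list(m = merge_loops(list(a = s1, b = s2)), c = L3))
  m1_23 <- merge_loops(list(a = s1, m = merge_loops(list(b = s2, c = L3))))
  expect_equal(keyset(m12_3), keyset(m1_23))
  expect_lte(nrow(m), nrow(s1) + nrow(s2))
})

test_that("loop counts equal brute-force rectangle sums", {
  set.seed(25)
  n <- 60
  m <- random_contact_dense(n)
  cm <- cm_from_dense(m, 25000, n * 25000)
  expect_equal(loop_counts(cm, mk_pairs("chr1", 5, 12)), m[6, 13])
  expect_equal(loop_counts(cm, mk_pairs("chr1", 0, 59)), m[1, 60])
  # multi-bin anchors: 2x2 rectangle
  wide <- data.table::data.table(chrom = "chr1", start1 = 5 * 25000,
                                 end1 = 7 * 25000, start2 = 20 * 25000,
                                 end2 = 22 * 25000, resolution = 50000,
                                 name = "W")
  expect_equal(loop_counts(cm, wide), sum(m[6:7, 21:22]))
  # randomized loops vs double-loop oracle
  loops <- mk_pairs("chr1", sample(0:30, 20), sample(35:59, 20))
  got <- loop_counts(cm, loops)
  oracle <- vapply(seq_len(20), function(i)
    m[loops$start1[i] / 25000 + 1, loops$start2[i] / 25000 + 1], numeric(1))
  expect_equal(got, oracle)
  out <- mk_pairs("chr1", 0, 70)
  expect_error(loop_counts(cm, out), "outside")
})

test_that("scaling to the smallest library preserves proportions exactly", {
  sc <- scale_to_smallest(cbind(a = c(10, 20), b = c(40, 10)), c(100, 50))
  expect_equal(unname(sc$factors), c(0.5, 1))
  expect_equal(unname(sc$scaled[, "a"]), c(5, 10))
  expect_equal(unname(sc$scaled[, "b"]), c(40, 10))
  eq <- scale_to_smallest(cbind(c(1, 2), c(3, 4)), c(7, 7))
  expect_true(all(eq$factors == 1))
  set.seed(33)
  counts <- matrix(rpois(300, 20), ncol = 3)
  totals <- c(9e5, 6e5, 7.5e5)
  sc2 <- scale_to_smallest(counts, totals)
  # scaled library totals all equal the smallest
  expect_equal(unname(colSums(sweep(counts, 2, totals / colSums(counts), `*`) *
                                rep(sc2$factors, each = 100))),
               rep(min(totals), 3) / 1, tolerance = 1e-9)
  # within-sample proportions unchanged
  expect_equal(sc2$scaled[, 1] / sum(sc2$scaled[, 1]),
               counts[, 1] / sum(counts[, 1]))
  expect_error(scale_to_smallest(counts, c(1, 2)), "per sample")
  expect_error(scale_to_smallest(counts, c(0, 1, 2)), "> 0")
})

test_that("differential loops classify on q and fold-change thresholds", {
  set.seed(41)
  n <- 200
  ref <- rpois(n, 50); obs <- rpois(n, 50)
  obs[1:10] <- rpois(10, 200)   # increased
  obs[11:20] <- rpois(10, 10)   # decreased
  loops <- mk_pairs("chr1", seq(0, 2 * n - 2, by = 2), seq(10, 2 * n + 8, by = 2))
  res <- differential_loops(loops, ref, obs, 1e6, 1e6)
  expect_true(all(res$class[res$q < 0.1 & res$FC > 2] == "increased"))
  expect_true(all(res$class[res$q < 0.1 & res$FC < 0.5] == "decreased"))
  expect_true(all(res$class[res$q >= 0.1] == "unchanged"))
  expect_true(all(res$class[1:10] == "increased"))
  expect_true(all(res$class[11:20] == "decreased"))
  # swapping the samples maps increased <-> decreased exactly
  swap <- differential_loops(loops, obs, ref, 1e6, 1e6)
  expect_identical(res$class == "increased", swap$class == "decreased")
  expect_identical(res$class == "decreased", swap$class == "increased")
  expect_equal(res$FC, 1 / swap$FC, tolerance = 1e-12)
  # the interaction core is the same classifier
  res_i <- differential_interactions(loops, ref, obs, 1e6, 1e6)
  expect_identical(res$class, res_i$class)
  expect_error(differential_loops(loops, c(NA, ref[-1]), obs, 1, 1), "missing")
})

test_that("multi-resolution merging keeps the finest complete overlap only", {
  lo <- data.table::data.table(chrom = "chr1", start1 = 0, end1 = 25000,
                               start2 = 100000, end2 = 125000,
                               resolution = 25000, name = "lo",
                               q_wt = 0.01, q_ko = 0.5)
  hi <- data.table::data.table(chrom = "chr1", start1 = 10000, end1 = 15000,
                               start2 = 110000, end2 = 115000,
                               resolution = 5000, name = "hi",
                               q_wt = 0.02, q_ko = 0.9)
  m <- merge_interactions_multires(list(lo, hi))
  expect_equal(m$name, "hi")

  # partial overlap keeps both records
  hi_part <- data.table::copy(hi)
  hi_part$start1 <- 20000; hi_part$end1 <- 25000
  hi_part$start2 <- 120000; hi_part$end2 <- 127000  # extends past the 25 kb anchor
  m2 <- merge_interactions_multires(list(lo, hi_part))
  expect_setequal(m2$name, c("lo", "hi"))

  # records significant in no sample are dropped
  lo_ns <- data.table::copy(lo); lo_ns$q_wt <- 0.5; lo_ns$q_ko <- 0.2
  m3 <- merge_interactions_multires(list(lo_ns, hi))
  expect_equal(m3$name, "hi")
  # significant in any one sample suffices
  lo_ko <- data.table::copy(lo_ns); lo_ko$q_ko <- 0.05
  lo_ko$start1 <- 50000; lo_ko$end1 <- 75000  # move away from hi
  lo_ko$start2 <- 200000; lo_ko$end2 <- 225000
  m4 <- merge_interactions_multires(list(lo_ko, hi))
  expect_setequal(m4$name, c("lo", "hi"))
})

test_that("anchor binding classification follows the documented precedence", {
  layout <- toy_layout(1, 1e7)
  loops <- mk_pairs("chr1", c(10, 50, 100), c(20, 60, 110))
  inc <- gr_feats(layout, "chr1", 10 * 25000 + 100, 10 * 25000 + 400)
  other <- gr_feats(layout, "chr1",
                    c(10 * 25000 + 1000, 60 * 25000 + 100),
                    c(10 * 25000 + 1400, 60 * 25000 + 400))
  all_peaks <- c(inc, other)
  cls <- classify_anchor_binding(loops, inc, all_peaks, layout)
  expect_equal(cls, c("increased", "unchanged", "none"))
})

test_that("features fall into loop spans with per-class counting and controls", {
  layout <- toy_layout(1, 1e7)
  loops <- mk_pairs("chr1", c(10, 100), c(20, 120))
  loops$class <- c("increased", "decreased")
  inside <- gr_feats(layout, "chr1", c(12 * 25000, 110 * 25000, 9e6),
                     c(12 * 25000 + 5000, 110 * 25000 + 5000, 9e6 + 5000),
                     name = c("g1", "g2", "g3"))
  res <- features_in_loops(inside, loops, layout)
  expect_equal(unname(res$distribution["increased"]), 1)
  expect_equal(unname(res$distribution["decreased"]), 1)
  expect_equal(unname(res$distribution["outside"]), 1)
  expect_true(res$membership$outside[3])

  # number-matched random controls are seeded draws from the universe
  set.seed(1)
  uni <- gr_feats(layout, "chr1", (0:199) * 50000, (0:199) * 50000 + 2000,
                  name = sprintf("u%d", 1:200))
  res2 <- features_in_loops(inside, loops, layout, universe = uni,
                            random_n = c(20, 10), seed = 3)
  expect_length(res2$random, 2)
  # every drawn feature is either outside or in at least one class
  in_any_1 <- 20 - unname(res2$random[[1]]["outside"])
  expect_gte(sum(res2$random[[1]][c("increased", "decreased", "unchanged")]),
             in_any_1)
  res3 <- features_in_loops(inside, loops, layout, universe = uni,
                            random_n = c(20, 10), seed = 3)
  expect_identical(res2$random, res3$random)
})
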