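test_that("rate-form Poisson tails reproduce the closed forms", {
  # P(X <= 0 | lambda = 5) = exp(-5)
  expect_equal(poisson_pairwise_test(5, 0, 1, 1, "decrease", pseudocount = 0,
                                     method = "rate"),
               exp(-5), tolerance = 1e-12)
  # upper tail equals the direct sum of the Poisson pmf
  direct <- sum(dpois(30:200, 10))
  expect_equal(poisson_pairwise_test(10, 30, 1, 1, "increase", pseudocount = 0,
                                     method = "rate"),
               direct, tolerance = 1e-10)
})

test_that("pairwise Poisson p-values depend on totals only through their ratio", {
  for (m in c("conditional", "rate")) {
    p1 <- poisson_pairwise_test(5, 7, 1000, 2000, "two_sided", method = m)
    p2 <- poisson_pairwise_test(5, 7, 2000, 4000, "two_sided", method = m)
    expect_identical(p1, p2)
  }
})

test_that("conditional pairwise test is exactly symmetric and calibrated", {
  set.seed(31)
  a <- rpois(300, 15); b <- rpois(300, 15)
  p_ab <- poisson_pairwise_test(a, b, 1e6, 1e6, "two_sided")
  p_ba <- poisson_pairwise_test(b, a, 1e6, 1e6, "two_sided")
  expect_identical(p_ab, p_ba)
  # unequal totals: tails still exchange bit-for-bit
  expect_identical(poisson_pairwise_test(a, b, 3e6, 1e6, "two_sided"),
                   poisson_pairwise_test(b, a, 1e6, 3e6, "two_sided"))
  # increase tail of (a -> b) equals decrease tail of (b -> a)
  expect_equal(poisson_pairwise_test(a, b, 1e6, 1e6, "increase"),
               poisson_pairwise_test(b, a, 1e6, 1e6, "decrease"),
               tolerance = 1e-12)
  # null fraction below alpha stays at or below alpha (discreteness allowed)
  aa <- rpois(20000, 20); bb <- rpois(20000, 20)
  p <- poisson_pairwise_test(aa, bb, 1, 1, "two_sided")
  expect_lt(mean(p < 0.05), 0.065)
  expect_lt(mean(p < 0.01), 0.015)
  expect_error(poisson_pairwise_test(-1, 3, 1, 1), "counts")
  expect_error(poisson_pairwise_test(1, 3, 0, 1), "totals")
})

test_that("one-tailed Fisher matches exhaustive enumeration and fisher.test", {
  # toy table (2,0; 0,2): enrichment tail = 1/6 by direct enumeration
  expect_equal(fisher_increase_test(0, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(fisher_increase_test(5, 0, 10, 10), 1, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:200) {
    tr <- sample.int(25, 1); to <- sample.int(25, 1)
    a <- sample.int(tr + 1, 1) - 1; b <- sample.int(to + 1, 1) - 1
    got <- fisher_increase_test(a, b, tr, to)
    expect_equal(got, fisher_oracle(a, b, tr, to), tolerance = 1e-10)
    ft <- fisher.test(matrix(c(b, to - b, a, tr - a), 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(got, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_increase_test(5, 1, 3, 10), "cells")
})

test_that("BH adjustment equals the textbook step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample.int(300, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(40)
  perm <- sample.int(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("tiered increased-peak calls are thresholded and nested", {
  set.seed(44)
  n <- 400
  counts <- data.frame(id = sprintf("p%d", 1:n),
                       count_ref = rpois(n, 30), count_obs = rpois(n, 30),
                       total_ref = 1e6, total_obs = 1e6)
  # plant unmistakable gains
  counts$count_obs[1:20] <- counts$count_ref[1:20] * 8 + 200
  res <- call_increased_peaks(counts, method = "fisher")
  expect_true(all(res$tier_high == (res$q < 1e-7)))
  expect_true(all(res$tier_medium == (res$q < 1e-5)))
  expect_true(all(res$tier_low == (res$q < 5e-4)))
  # nesting: high implies medium implies low, for every peak
  expect_true(all(!res$tier_high | res$tier_medium))
  expect_true(all(!res$tier_medium | res$tier_low))
  expect_true(all(res$class[res$tier_low] == "increased"))
  expect_true(all(res$id[1:20] %in% res$id[res$tier_high]))
  expect_error(call_increased_peaks(counts[0, ]), "empty")

  # poisson and fisher variants agree on what is overwhelming
  res_p <- call_increased_peaks(counts, method = "poisson")
  expect_true(all(res_p$tier_low[1:20]))
})

test_that("dysregulation classes follow the q and fold-change thresholds", {
  # construct counts with known, extreme directions plus nulls
  set.seed(4)
  n <- 300
  counts <- data.frame(id = sprintf("g%d", 1:n),
                       count_ref = rpois(n, 100), count_obs = rpois(n, 100),
                       total_ref = 1e5, total_obs = 1e5)
  counts$count_obs[1:10] <- rpois(10, 500)
  counts$count_obs[11:20] <- rpois(10, 10)
  for (kind in c("gene", "repeat")) {
    res <- call_dysregulated(counts, kind)
    thr <- if (kind == "gene") 0.001 else 0.01
    expect_true(all(res$class[res$q < thr & res$FC > 2] == "up"))
    expect_true(all(res$class[res$q < thr & res$FC < 0.5] == "down"))
    expect_true(all(res$class[res$q >= thr] == "unchanged"))
    expect_true(all(res$class[1:10] == "up"))
    expect_true(all(res$class[11:20] == "down"))
  }
  # q below threshold but modest fold change stays unchanged
  mild <- data.frame(id = "x", count_ref = 10000, count_obs = 11000,
                     total_ref = 1e6, total_obs = 1e6)
  expect_equal(call_dysregulated(mild, "gene")$class, "unchanged")
})

test_that("number-matched random sampling is uniform, seeded and exclusive", {
  layout <- toy_layout(1, 1e6)
  n_uni <- 40
  uni <- gr_feats(layout, "chr1", (0:(n_uni - 1)) * 1000,
                  (0:(n_uni - 1)) * 1000 + 500,
                  name = sprintf("u%d", 1:n_uni))
  excl <- uni[1:10]
  s1 <- sample_matched_random(uni, excl, 5, seed = 7)
  s2 <- sample_matched_random(uni, excl, 5, seed = 7)
  expect_identical(features_to_dt(s1), features_to_dt(s2))
  expect_false(any(S4Vectors::mcols(s1)$name %in% S4Vectors::mcols(excl)$name))
  # n equal to the whole remainder returns the remainder
  all30 <- sample_matched_random(uni, excl, 30, seed = 1)
  expect_setequal(S4Vectors::mcols(all30)$name,
                  S4Vectors::mcols(uni)$name[11:40])
  expect_error(sample_matched_random(uni, excl, 31, seed = 1), "need")

  # selection frequency approximately n / |eligible| per eligible feature
  freq <- integer(n_uni)
  for (s in 1:400) {
    picked <- sample_matched_random(uni, NULL, 8, seed = s)
    idx <- match(S4Vectors::mcols(picked)$name, S4Vectors::mcols(uni)$name)
    freq[idx] <- freq[idx] + 1
  }
  expected <- 400 * 8 / n_uni
  expect_true(all(abs(freq - expected) < 5 * sqrt(expected)))
})
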