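# A small configuration exercising every planted structure quickly.
small_cfg <- function(...) {
  sim_config(n_chrom = 1, chrom_length = 10e6, n_peaks = 600, n_gain = 60,
             n_cooccur_ctcf = 60, n_cooccur_k9 = 60, n_k9_only = 120,
             n_genes = 150, n_repeats = 400, n_genes_up = 20,
             n_genes_down = 10, n_repeats_up = 30, n_repeats_down = 15,
             n_loops = 60, n_loop_gain = 10, n_switch_blocks = 4,
             n_tads_per_chrom = 4, ...)
}

test_that("generation is fully deterministic under a seed", {
  t1 <- simulate_genome(small_cfg(), seed = 11)
  t2 <- simulate_genome(small_cfg(), seed = 11)
  for (tab in c("ctcf_peaks", "k9_sites", "genes", "repeats", "compartments",
                "switch_blocks", "tad_boundaries", "loops")) {
    expect_identical(t1[[tab]], t2[[tab]])
  }
  t3 <- simulate_genome(small_cfg(), seed = 12)
  expect_false(identical(t1$ctcf_peaks, t3$ctcf_peaks))

  e1 <- simulate_expression(t1, "KO", seed = 11)
  e2 <- simulate_expression(t1, "KO", seed = 11)
  expect_identical(e1, e2)
  k1 <- simulate_tracks(t1, "WT", seed = 11)
  k2 <- simulate_tracks(t1, "WT", seed = 11)
  expect_identical(k1$tracks$ctcf$values, k2$tracks$ctcf$values)
  c1 <- simulate_contacts(t1, "KO", seed = 11)
  c2 <- simulate_contacts(t1, "KO", seed = 11)
  expect_identical(as.matrix(c1$map$mats$chr1), as.matrix(c2$map$mats$chr1))
})

test_that("configured counts and class mixtures are honored exactly", {
  cfg <- small_cfg()
  truth <- simulate_genome(cfg, seed = 3)
  expect_equal(nrow(truth$ctcf_peaks), 600)
  expect_equal(sum(truth$ctcf_peaks$category == "gained"), 60)
  expect_equal(nrow(truth$genes), 150)
  expect_equal(sum(truth$genes$dysreg == "up"), 20)
  expect_equal(sum(truth$genes$dysreg == "down"), 10)
  # repeat classes hit their configured shares exactly
  tab <- table(truth$repeats$class)
  expect_equal(unname(tab["SINE_B2"]), 0.35 * 400)
  expect_equal(sum(tab), 400)
  # genes are non-overlapping
  g <- truth$genes
  expect_true(all(g$start[-1] >= g$end[-nrow(g)] | g$chrom[-1] != g$chrom[-nrow(g)]))
  # layout honoured
  expect_equal(unname(truth$layout$lengths), 10e6)
  # infeasible packing is an error
  expect_error(simulate_genome(sim_config(n_chrom = 1, chrom_length = 1e6,
                                          n_peaks = 5000), seed = 1),
               "packing")
  expect_error(simulate_genome(small_cfg(n_switch_blocks = 200), seed = 1),
               "packing")
})

test_that("truth report round-trips through TSV", {
  truth <- simulate_genome(small_cfg(), seed = 5)
  dir <- withr::local_tempdir()
  truth_report(truth, dir)
  back <- read_truth_report(dir)
  expect_equal(nrow(back$ctcf_peaks), nrow(truth$ctcf_peaks))
  expect_equal(back$loops$ratio, truth$loops$ratio)
  expect_equal(back$genes$fc, truth$genes$fc)
  expect_identical(back$compartments$wt_label, truth$compartments$wt_label)
  # every planted peak appears exactly once
  expect_false(any(duplicated(back$ctcf_peaks$name)))
})

test_that("planted track effects hit their configured ratios in the mean", {
  for (ratio in c(1, 4)) {
    cfg <- small_cfg(gain_ratio = ratio)
    truth <- simulate_genome(cfg, seed = 21)
    tw <- simulate_tracks(truth, "WT", seed = 21)
    tk <- simulate_tracks(truth, "KO", seed = 21)
    peaks <- tw$peaks$ctcf[truth$ctcf_peaks$category == "gained"]
    cw <- count_in_features(tw$tracks$ctcf, peaks)
    ck <- count_in_features(tk$tracks$ctcf, peaks)
    # background inside the peak window dilutes the ratio slightly
    est <- mean(ck) / mean(cw)
    expect_lt(abs(est - ratio) / ratio, 0.1)
  }
  # input track carries no site signal: flat mean at the background rate
  cfg <- small_cfg()
  truth <- simulate_genome(cfg, seed = 8)
  ti <- simulate_tracks(truth, "WT", seed = 8)
  expect_lt(abs(mean(ti$tracks$input$values$chr1) - cfg$background_rate), 0.01)
})

test_that("a decay-only contact map has O/E near one everywhere informative", {
  cfg <- small_cfg(comp_same = 1, comp_diff = 1, tad_boost = 1, n_loops = 0,
                   n_loop_gain = 0, n_switch_blocks = 0, hic_depth = 200)
  truth <- simulate_genome(cfg, seed = 2)
  sim <- simulate_contacts(truth, "WT", seed = 2)
  oe <- observed_expected(sim$map)$chr1
  near <- oe$oe[abs(row(oe$oe) - col(oe$oe)) < 50]
  expect_lt(abs(mean(near, na.rm = TRUE) - 1), 0.05)
})

test_that("planted loop intensities scale knockout counts by the ratio", {
  cfg <- small_cfg(n_loop_gain = 20, loop_change_ratio = 3,
                   n_switch_blocks = 0)
  truth <- simulate_genome(cfg, seed = 31)
  hw <- simulate_contacts(truth, "WT", seed = 31)
  hk <- simulate_contacts(truth, "KO", seed = 31)
  cw <- loop_counts(hw$map, truth$loops)
  ck <- loop_counts(hk$map, truth$loops)
  gained <- truth$loops$ratio > 1
  est <- mean(ck[gained]) / mean(cw[gained])
  expect_lt(abs(est - 3) / 3, 0.15)
  est_null <- mean(ck[!gained]) / mean(cw[!gained])
  expect_lt(abs(est_null - 1), 0.1)
  # exact expected ratios from the rate model agree with the plan
  rr <- loop_expected_ratio(truth, truth$loops)
  expect_equal(rr[gained], rep(3, sum(gained)))
  expect_true(all(rr[!gained] == 1))
})

test_that("expression effects are recovered end to end", {
  truth <- simulate_genome(small_cfg(), seed = 41)
  ew <- simulate_expression(truth, "WT", seed = 41)
  ek <- simulate_expression(truth, "KO", seed = 41)
  counts <- data.frame(id = ew$genes$id, count_ref = ew$genes$count,
                       count_obs = ek$genes$count,
                       total_ref = unname(ew$totals["genes"]),
                       total_obs = unname(ek$totals["genes"]))
  res <- call_dysregulated(counts, "gene")
  up_truth <- truth$genes$name[truth$genes$dysreg == "up"]
  expect_gte(mean(res$class[res$id %in% up_truth] == "up"), 0.9)
  # under an all-null configuration fold-change estimates centre on 1
  # (with planted effects the library totals carry a composition bias)
  tn <- simulate_genome(small_cfg(gene_fc = 1, repeat_fc = 1, n_genes_up = 0,
                                  n_genes_down = 0, n_repeats_up = 0,
                                  n_repeats_down = 0), seed = 42)
  ewn <- simulate_expression(tn, "WT", seed = 42)
  ekn <- simulate_expression(tn, "KO", seed = 42)
  fcn <- fc_est <- ((ekn$genes$count + 1) / ekn$totals["genes"]) /
    ((ewn$genes$count + 1) / ewn$totals["genes"])
  expect_lt(abs(median(fcn) - 1), 0.05)
})
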