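#!/usr/bin/env Rscript
# Mutual exclusivity of H3K9me3 and CTCF over 5 kb co-occupancy windows
# (windows holding peaks of both marks in at least one sample), plus a
# k-means view (k = 8) of the window signal matrix.

suppressMessages(library(archdelta))
seed <- 1
dir.create("results", showWarnings = FALSE)

truth <- simulate_genome(sim_config(), seed = seed)
tw <- simulate_tracks(truth, "WT", seed = seed)
tk <- simulate_tracks(truth, "KO", seed = seed)
rpkm <- function(trk, inp) input_subtract(counts_to_rpkm(trk), counts_to_rpkm(inp))

tab <- cooccupancy_windows(
  peaks_A = list(tw$peaks$h3k9me3, tk$peaks$h3k9me3),
  peaks_B = list(tw$peaks$ctcf, tk$peaks$ctcf),
  window_size = 5000, layout = truth$layout,
  tracks = list(k9_wt = rpkm(tw$tracks$h3k9me3, tw$tracks$input),
                ctcf_wt = rpkm(tw$tracks$ctcf, tw$tracks$input),
                k9_ko = rpkm(tk$tracks$h3k9me3, tk$tracks$input),
                ctcf_ko = rpkm(tk$tracks$ctcf, tk$tracks$input)))
data.table::fwrite(tab, "results/cooccupancy_windows.tsv", sep = "\t")
message(nrow(tab), " co-occupied 5 kb windows")

for (cond in c("wt", "ko")) {
  s <- exclusivity_summary(tab, paste0("signal_k9_", cond),
                           paste0("signal_ctcf_", cond))
  message(sprintf("%s: Pearson r = %.3f, double-high fraction = %.4f (n = %d)",
                  toupper(cond), s$r, s$double_high_fraction, s$n_windows))
}

mat <- as.matrix(tab[, c("signal_k9_wt", "signal_ctcf_wt",
                         "signal_k9_ko", "signal_ctcf_ko")])
cl <- cluster_rows(mat, k = 8, seed = seed)
data.table::fwrite(
  data.table::data.table(tab[, c("chrom", "start", "end")],
                         cluster = cl$labels),
  "results/window_clusters_k8.tsv", sep = "\t")
message("k-means (k = 8) cluster sizes: ",
        paste(table(cl$labels), collapse = " "))
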