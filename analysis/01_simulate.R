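#!/usr/bin/env Rscript
# Generate the paired-condition synthetic dataset (WT vs KO) with planted
# truth, and write every input in its on-disk exchange format, so the later
# stages can be replayed from files alone.

suppressMessages(library(archdelta))
seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- simulate_genome(sim_config(), seed = seed)
print(truth)
truth_report(truth, file.path(out, "truth"))

for (cond in c("WT", "KO")) {
  tr <- simulate_tracks(truth, cond, seed = seed)
  for (mark in names(tr$tracks))
    write_track(tr$tracks[[mark]], file.path(out, sprintf("%s_%s.bedgraph", cond, mark)))
  write_intervals(tr$peaks$ctcf, file.path(out, sprintf("%s_ctcf_peaks.bed", cond)))
  write_intervals(tr$peaks$h3k9me3, file.path(out, sprintf("%s_h3k9me3_peaks.bed", cond)))
  hc <- simulate_contacts(truth, cond, seed = seed)
  write_contacts(hc$map, file.path(out, sprintf("%s_contacts.coo", cond)))
  write_pairs(hc$loops, file.path(out, sprintf("%s_loops.bedpe", cond)))
  for (res in names(hc$interactions))
    data.table::fwrite(hc$interactions[[res]],
                       file.path(out, sprintf("%s_interactions_%s.tsv", cond, res)),
                       sep = "\t")
  ex <- simulate_expression(truth, cond, seed = seed)
  data.table::fwrite(ex$genes, file.path(out, sprintf("%s_gene_counts.tsv", cond)), sep = "\t")
  data.table::fwrite(ex$repeats, file.path(out, sprintf("%s_repeat_counts.tsv", cond)), sep = "\t")
  message(sprintf("%s: %.3g ChIP reads (CTCF), %.4g Hi-C contacts, %d loops",
                  cond, tr$tracks$ctcf$library_total, hc$map$total, nrow(hc$loops)))
}
message("wrote ", length(list.files(out, recursive = TRUE)), " files under ", out)
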