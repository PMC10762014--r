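#!/usr/bin/env Rscript
# Dysregulated genes (q < 0.001, |FC| > 2) and individual repeats
# (q < 0.01, |FC| > 2) between KO and WT, with recovery against the
# planted truth.

suppressMessages(library(archdelta))
seed <- 1
dir.create("results", showWarnings = FALSE)

truth <- simulate_genome(sim_config(), seed = seed)
ew <- simulate_expression(truth, "WT", seed = seed)
ek <- simulate_expression(truth, "KO", seed = seed)

for (kind in c("genes", "repeats")) {
  cc <- data.frame(id = ew[[kind]]$id, count_ref = ew[[kind]]$count,
                   count_obs = ek[[kind]]$count,
                   total_ref = unname(ew$totals[kind]),
                   total_obs = unname(ek$totals[kind]))
  res <- call_dysregulated(cc, ifelse(kind == "genes", "gene", "repeat"))
  data.table::fwrite(res, sprintf("results/dysregulated_%s.tsv", kind),
                     sep = "\t")
  tt <- if (kind == "genes") truth$genes else truth$repeats
  planted_up <- tt$name[tt$dysreg == "up"]
  planted_down <- tt$name[tt$dysreg == "down"]
  message(sprintf(
    "%s: %d up / %d down called; planted-up recovery %.2f, planted-down %.2f",
    kind, sum(res$class == "up"), sum(res$class == "down"),
    mean(res$class[res$id %in% planted_up] == "up"),
    mean(res$class[res$id %in% planted_down] == "down")))
}
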