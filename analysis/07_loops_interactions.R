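#!/usr/bin/env Rscript
# Chromatin loops and significant interactions: exact-anchor merging across
# conditions, per-loop counts, scaled-count Poisson differential test
# (q < 0.1, |FC| > 2), anchor CTCF classification, genes-in-loops with
# number-matched random controls, multi-resolution interaction merging and
# the within-loop differential-interaction report.

suppressMessages(library(archdelta))
seed <- 1
dir.create("results", showWarnings = FALSE)

truth <- simulate_genome(sim_config(), seed = seed)
layout <- truth$layout
hw <- simulate_contacts(truth, "WT", seed = seed)
hk <- simulate_contacts(truth, "KO", seed = seed)

merged <- merge_loops(list(WT = hw$loops, KO = hk$loops))
dl <- differential_loops(merged, loop_counts(hw$map, merged),
                         loop_counts(hk$map, merged),
                         hw$map$total, hk$map$total)
data.table::fwrite(dl, "results/differential_loops.tsv", sep = "\t")
message(sprintf("loops: %d merged, %d increased, %d decreased",
                nrow(dl), sum(dl$class == "increased"),
                sum(dl$class == "decreased")))

# anchor CTCF classification uses the increased peaks from stage 02
tw <- simulate_tracks(truth, "WT", seed = seed)
tk <- simulate_tracks(truth, "KO", seed = seed)
counts <- data.frame(
  id = truth$ctcf_peaks$name,
  count_ref = count_in_features(tw$tracks$ctcf, tw$peaks$ctcf),
  count_obs = count_in_features(tk$tracks$ctcf, tw$peaks$ctcf),
  total_ref = tw$tracks$ctcf$library_total,
  total_obs = tk$tracks$ctcf$library_total)
pk <- call_increased_peaks(counts, method = "fisher")
inc_peaks <- tw$peaks$ctcf[pk$tier_low]
dl$anchor_class <- classify_anchor_binding(dl, inc_peaks, tw$peaks$ctcf, layout)
print(table(loop = dl$class, anchor = dl$anchor_class))

# genes falling into classified loop spans, with two number-matched draws
ew <- simulate_expression(truth, "WT", seed = seed)
ek <- simulate_expression(truth, "KO", seed = seed)
gc <- data.frame(id = ew$genes$id, count_ref = ew$genes$count,
                 count_obs = ek$genes$count,
                 total_ref = unname(ew$totals["genes"]),
                 total_obs = unname(ek$totals["genes"]))
dg <- call_dysregulated(gc, "gene")
genes_gr <- make_features(as.data.frame(truth$genes), layout)
up_gr <- genes_gr[S4Vectors::mcols(genes_gr)$name %in% dg$id[dg$class == "up"]]
down_gr <- genes_gr[S4Vectors::mcols(genes_gr)$name %in% dg$id[dg$class == "down"]]
fil <- features_in_loops(up_gr, dl, layout, universe = genes_gr,
                         random_n = c(length(up_gr), length(down_gr)),
                         seed = seed)
message("up-regulated genes in loops: ",
        paste(names(fil$distribution), fil$distribution, collapse = ", "))
message("random control #1:          ",
        paste(names(fil$random[[1]]), fil$random[[1]], collapse = ", "))

# multi-resolution significant interactions and their differential test
calls <- lapply(names(hw$interactions), function(res) {
  w <- hw$interactions[[res]]; k <- hk$interactions[[res]]
  data.table::data.table(w[, c("chrom", "start1", "end1", "start2", "end2",
                               "resolution", "name")],
                         q_wt = w$q, q_ko = k$q,
                         count_wt = w$count, count_ko = k$count)
})
mi <- merge_interactions_multires(calls)
di <- differential_interactions(mi, mi$count_wt, mi$count_ko,
                                hw$map$total, hk$map$total)
data.table::fwrite(di, "results/differential_interactions.tsv", sep = "\t")
message(sprintf("interactions: %d retained after multi-resolution merge, %d increased, %d decreased",
                nrow(di), sum(di$class == "increased"),
                sum(di$class == "decreased")))

# descriptive: fraction of altered loops with a differential interaction
# strictly inside the loop span
altered <- dl[dl$class != "unchanged"]
dsig <- di[di$class != "unchanged"]
if (nrow(altered) > 0) {
  has_inside <- vapply(seq_len(nrow(altered)), function(i) {
    any(dsig$chrom == altered$chrom[i] &
          dsig$start1 >= altered$start1[i] & dsig$end2 <= altered$end2[i])
  }, logical(1))
  message(sprintf("altered loops containing a differential interaction within the span: %.1f%%",
                  100 * mean(has_inside)))
}
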