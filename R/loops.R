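anchor_key <- function(p) {
  paste(p$chrom, p$start1, p$end1, p$start2, p$end2, sep = ":")
}

#' Merge loop sets on exact anchors
#'
#' Loops called from different samples with exactly the same anchor
#' coordinates are merged to a single definition; provenance records which
#' samples called each loop. Idempotent and associative.
#'
#' @param sets Named list of anchor-pair tables (as from [read_pairs()]).
#' @return data.table of unique loops with a `called_in` provenance column.
#' @export
merge_loops <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("sample", seq_along(sets))
  pooled <- data.table::rbindlist(lapply(names(sets), function(s) {
    p <- sets[[s]]
    if (nrow(p) == 0) return(NULL)
    data.table::data.table(chrom = p$chrom, start1 = p$start1, end1 = p$end1,
                           start2 = p$start2, end2 = p$end2,
                           resolution = p$resolution, sample = s)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) return(read_pairs_empty())
  pooled$key <- anchor_key(pooled)
  merged <- pooled[, list(
    chrom = chrom[1], start1 = start1[1], end1 = end1[1],
    start2 = start2[1], end2 = end2[1], resolution = resolution[1],
    called_in = paste(sort(unique(sample)), collapse = ",")), by = "key"]
  merged$key <- NULL
  data.table::setorder(merged, chrom, start1, start2)
  merged$name <- sprintf("loop_%d", seq_len(nrow(merged)))
  ad_log("merge_loops: %d unique loops from %d records", nrow(merged), nrow(pooled))
  merged
}

#' Raw contact counts per loop
#'
#' Sums the contact-matrix cells whose bin pair falls in the anchor1 x
#' anchor2 rectangle of each loop.
#'
#' @param cm A [contact_map()]; the map bin size must divide the anchor
#'   resolution.
#' @param loops Anchor-pair table.
#' @return Numeric vector of per-loop counts.
#' @export
loop_counts <- function(cm, loops) {
  stopifnot(inherits(cm, "contact_map"))
  counts <- numeric(nrow(loops))
  for (chrom in unique(loops$chrom)) {
    if (!chrom %in% names(cm$mats)) stop(sprintf("no contacts for %s", chrom))
    m <- cm$mats[[chrom]]
    nb <- nrow(m)
    sel <- which(loops$chrom == chrom)
    for (i in sel) {
      b1 <- (loops$start1[i] %/% cm$bin_size):((loops$end1[i] - 1) %/% cm$bin_size) + 1L
      b2 <- (loops$start2[i] %/% cm$bin_size):((loops$end2[i] - 1) %/% cm$bin_size) + 1L
      if (max(b1, b2) > nb || min(b1, b2) < 1L)
        stop(sprintf("loop %d anchor outside the contact map", i))
      # anchors are genome-ordered, so the rectangle lies in the stored
      # upper triangle; include the mirrored part for anchor overlaps
      counts[i] <- sum(m[b1, b2]) + sum(m[b2, b1]) -
        sum(m[intersect(b1, b2), intersect(b1, b2)])
    }
  }
  counts
}

#' Scale per-sample counts to the smallest library
#'
#' Multiplies every sample's counts by `min(totals) / total_s`, so scaled
#' library totals are equal across samples while within-sample proportions
#' are preserved exactly.
#'
#' @param counts Matrix or data.frame (units x samples).
#' @param totals Per-sample library totals (> 0).
#' @return List with `scaled` (matrix), `factors` and `scaled_total`.
#' @export
scale_to_smallest <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (length(totals) != ncol(counts))
    stop("one total per sample column required")
  if (any(totals <= 0)) stop("totals must be > 0")
  factors <- min(totals) / totals
  scaled <- sweep(counts, 2, factors, `*`)
  list(scaled = scaled, factors = factors, scaled_total = min(totals))
}

# Shared differential core for loops and interactions: two-sided Poisson on
# scaled counts (real-valued rate from the scaled reference, observed count
# rounded to the nearest integer), BH within the family, and (q, FC)
# threshold classification.
differential_pairs_core <- function(pairs, count_ref, count_obs,
                                    total_ref, total_obs,
                                    q_threshold = 0.1, fc_threshold = 2,
                                    pseudocount = 1) {
  if (anyNA(count_ref) || anyNA(count_obs)) stop("missing counts")
  sc <- scale_to_smallest(cbind(ref = count_ref, obs = count_obs),
                          c(total_ref, total_obs))
  sref <- sc$scaled[, "ref"]; sobs <- sc$scaled[, "obs"]
  p <- poisson_pairwise_test(sref, round(sobs), sc$scaled_total,
                             sc$scaled_total, direction = "two_sided",
                             pseudocount = pseudocount)
  q <- bh_adjust(p)
  fc <- fold_change(sref, sobs, sc$scaled_total, sc$scaled_total, pseudocount)
  class <- ifelse(q < q_threshold & fc > fc_threshold, "increased",
                  ifelse(q < q_threshold & fc < 1 / fc_threshold, "decreased",
                         "unchanged"))
  out <- data.table::as.data.table(pairs)
  out$count_ref <- count_ref; out$count_obs <- count_obs
  out$scaled_ref <- sref; out$scaled_obs <- sobs
  out$p <- p; out$q <- q; out$FC <- fc; out$class <- class
  out
}

#' Differential chromatin loops
#'
#' Two-sided Poisson pairwise test on library-scaled loop contact counts
#' (reference = WT, observed = KO), BH across all loops, and classification:
#' increased when `q < 0.1` and `FC > 2`, decreased when `q < 0.1` and
#' `FC < 0.5`, otherwise unchanged.
#'
#' @param loops Anchor-pair table (merged loop definitions).
#' @param count_ref,count_obs Raw per-loop contact counts in each sample.
#' @param total_ref,total_obs Total Hi-C contacts per sample.
#' @param q_threshold,fc_threshold Classification thresholds (defaults 0.1
#'   and 2).
#' @param pseudocount Pseudocount for rate and fold change (default 1).
#' @return data.table of loops with scaled counts, p, q, FC and class.
#' @export
differential_loops <- function(loops, count_ref, count_obs,
                               total_ref, total_obs,
                               q_threshold = 0.1, fc_threshold = 2,
                               pseudocount = 1) {
  out <- differential_pairs_core(loops, count_ref, count_obs, total_ref,
                                 total_obs, q_threshold, fc_threshold,
                                 pseudocount)
  ad_log("differential_loops: %d loops, %d increased, %d decreased",
         nrow(out), sum(out$class == "increased"), sum(out$class == "decreased"))
  out
}

#' Differential significant interactions
#'
#' Identical statistical core to [differential_loops()] applied to
#' multi-resolution significant interactions (counts already scaled to the
#' smallest contact total by the shared core); BH is applied within the
#' interaction family, separately from loops.
#'
#' @inheritParams differential_loops
#' @param interactions Interaction anchor-pair table (e.g. from
#'   [merge_interactions_multires()]).
#' @return data.table with p, q, FC and class per interaction.
#' @export
differential_interactions <- function(interactions, count_ref, count_obs,
                                      total_ref, total_obs,
                                      q_threshold = 0.1, fc_threshold = 2,
                                      pseudocount = 1) {
  differential_pairs_core(interactions, count_ref, count_obs, total_ref,
                          total_obs, q_threshold, fc_threshold, pseudocount)
}

#' Multi-resolution merging of significant interactions
#'
#' Keeps interactions significant (`q < q_keep`) in at least one sample, then
#' removes every lower-resolution record for which some retained
#' higher-resolution record has both anchors fully contained within the
#' lower-resolution record's anchors ("completely overlapped"); partial
#' overlaps keep both records. Output is coordinate-sorted.
#'
#' @param calls List of interaction tables, one per resolution, each with
#'   anchor columns plus one or more `q_*` per-sample significance columns.
#' @param q_keep Significance threshold (default 0.1).
#' @return data.table of retained interactions.
#' @export
merge_interactions_multires <- function(calls, q_keep = 0.1) {
  kept <- lapply(calls, function(dt) {
    dt <- data.table::as.data.table(dt)
    qcols <- grep("^q_", names(dt), value = TRUE)
    if (length(qcols) == 0) stop("interaction tables need q_* columns")
    sig <- Reduce(`|`, lapply(qcols, function(col) dt[[col]] < q_keep))
    dt[sig]
  })
  kept <- kept[vapply(kept, nrow, integer(1)) > 0]
  if (length(kept) == 0) return(read_pairs_empty())
  res <- vapply(kept, function(dt) dt$resolution[1], numeric(1))
  kept <- kept[order(res)]  # finest first
  res <- sort(res)
  keep_rows <- lapply(kept, function(dt) rep(TRUE, nrow(dt)))
  for (lo in seq_along(kept)) {
    for (hi in seq_len(lo - 1)) {  # hi indexes a finer resolution
      lo_dt <- kept[[lo]]; hi_dt <- kept[[hi]][keep_rows[[hi]]]
      if (nrow(hi_dt) == 0) next
      contained <- vapply(seq_len(nrow(lo_dt)), function(i) {
        any(hi_dt$chrom == lo_dt$chrom[i] &
              hi_dt$start1 >= lo_dt$start1[i] & hi_dt$end1 <= lo_dt$end1[i] &
              hi_dt$start2 >= lo_dt$start2[i] & hi_dt$end2 <= lo_dt$end2[i])
      }, logical(1))
      keep_rows[[lo]] <- keep_rows[[lo]] & !contained
    }
  }
  out <- data.table::rbindlist(
    lapply(seq_along(kept), function(i) kept[[i]][keep_rows[[i]]]),
    fill = TRUE)
  data.table::setorder(out, chrom, start1, start2)
  ad_log("merge_interactions_multires: %d retained", nrow(out))
  out
}

#' Anchor CTCF-binding classification of loops
#'
#' Classifies each loop by the binding at its anchors: `increased` if at
#' least one increased peak overlaps either anchor (precedence over all
#' else), otherwise `unchanged` if any other peak overlaps either anchor,
#' otherwise `none`.
#'
#' @param loops Anchor-pair table.
#' @param increased_peaks,all_peaks `GRanges` peak sets (`all_peaks` is the
#'   full peak universe; non-increased peaks are derived from it).
#' @param layout A [genome_layout()].
#' @return Character vector of per-loop anchor classes.
#' @export
classify_anchor_binding <- function(loops, increased_peaks, all_peaks, layout) {
  anch <- function(s, e) GenomicRanges::GRanges(
    seqnames = loops$chrom, ranges = IRanges::IRanges(start = s + 1L, end = e),
    seqinfo = layout_seqinfo(layout))
  a1 <- anch(loops$start1, loops$end1)
  a2 <- anch(loops$start2, loops$end2)
  hit <- function(peaks) {
    GenomicRanges::countOverlaps(a1, peaks) > 0 |
      GenomicRanges::countOverlaps(a2, peaks) > 0
  }
  inc <- hit(increased_peaks)
  any_peak <- hit(all_peaks)
  ifelse(inc, "increased", ifelse(any_peak, "unchanged", "none"))
}

#' Features falling into classified loops
#'
#' A feature "falls into" a loop when it overlaps (>= 1 bp) the loop span
#' `[anchor1 start, anchor2 end]`. Each loop class is counted at most once
#' per feature. Optionally draws number-matched random feature sets from a
#' universe and tabulates their class distributions alongside.
#'
#' @param features `GRanges` feature set (e.g. up-regulated genes).
#' @param loops Classified loop table (with a `class` column).
#' @param layout A [genome_layout()].
#' @param universe Optional `GRanges` universe for random controls.
#' @param random_n Integer vector of control draw sizes (one draw per
#'   element).
#' @param seed Integer seed for the random draws.
#' @return List with `membership` (per-feature logical flags per loop class
#'   and `outside`), `distribution` (counts per class), and `random` (list
#'   of control distributions).
#' @export
features_in_loops <- function(features, loops, layout, universe = NULL,
                              random_n = NULL, seed = 1) {
  spans_by_class <- function(cls) {
    sel <- loops$class == cls
    GenomicRanges::GRanges(
      seqnames = loops$chrom[sel],
      ranges = IRanges::IRanges(start = loops$start1[sel] + 1L,
                                end = loops$end2[sel]),
      seqinfo = layout_seqinfo(layout))
  }
  classes <- c("increased", "decreased", "unchanged")
  tabulate_set <- function(feats) {
    flags <- vapply(classes, function(cls)
      GenomicRanges::countOverlaps(feats, spans_by_class(cls)) > 0,
      logical(length(feats)))
    flags <- matrix(flags, ncol = length(classes),
                    dimnames = list(NULL, classes))
    outside <- rowSums(flags) == 0
    list(flags = flags, outside = outside,
         distribution = c(colSums(flags), outside = sum(outside)))
  }
  obs <- tabulate_set(features)
  rnd <- list()
  if (!is.null(random_n) && !is.null(universe)) {
    for (i in seq_along(random_n)) {
      draw <- sample_matched_random(universe, exclude = NULL, n = random_n[i],
                                    seed = sub_seed(seed, paste0("draw", i)))
      rnd[[i]] <- tabulate_set(draw)$distribution
    }
  }
  list(membership = data.table::data.table(
         name = S4Vectors::mcols(features)$name,
         obs$flags, outside = obs$outside),
       distribution = obs$distribution,
       random = rnd)
}
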