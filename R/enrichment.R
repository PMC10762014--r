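#' Exact hypergeometric test
#'
#' Tail probabilities for drawing `k` successes in `n` draws from a universe
#' of `N` containing `K` successes. `greater`/`less` are exact tail sums;
#' `two_sided` uses the minimum-likelihood convention: the sum of the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param k Observed overlap.
#' @param n Number of draws.
#' @param K Successes in the universe.
#' @param N Universe size.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return Exact p-value.
#' @export
hypergeom_test <- function(k, n, K, N, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (n > N || K > N || k > min(n, K) || k < max(0, n + K - N) ||
      any(c(k, n, K, N) < 0))
    stop("inconsistent hypergeometric arguments")
  switch(tail,
    greater = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    less = stats::phyper(k, K, N - K, n, lower.tail = TRUE),
    two_sided = {
      support <- max(0, n + K - N):min(n, K)
      d <- stats::dhyper(support, K, N - K, n)
      dk <- stats::dhyper(k, K, N - K, n)
      # relative tolerance guards against ties broken by rounding
      sum(d[d <= dk * (1 + 1e-7)])
    })
}

#' Repeat-class composition of a peak set
#'
#' Assigns every peak the class of its largest-overlap repeat annotation
#' (ties broken by overlap length, then by annotation start), or
#' `"unannotated"` when no repeat overlaps. Reports counts and proportions
#' for the peak set and, when given, for a reference universe of peaks.
#'
#' @param peaks `GRanges` peak set.
#' @param repeats `GRanges` repeat annotation with an mcols `class` column.
#' @param universe Optional `GRanges` reference peak set for side-by-side
#'   composition.
#' @return List with `table` (class, count, proportion and, with a universe,
#'   `universe_count`/`universe_proportion`) and `peak_class` (per input
#'   peak).
#' @export
repeat_composition <- function(peaks, repeats, universe = NULL) {
  stopifnot("class" %in% colnames(S4Vectors::mcols(repeats)))
  peak_class <- assign_largest_overlap_class(peaks, repeats)
  tab <- table(factor(peak_class))
  out <- data.table::data.table(class = names(tab),
                                count = as.integer(tab),
                                proportion = as.numeric(tab) / length(peaks))
  if (!is.null(universe)) {
    ucls <- assign_largest_overlap_class(universe, repeats)
    utab <- table(factor(ucls, levels = union(names(tab), unique(ucls))))
    out <- data.table::merge.data.table(
      out,
      data.table::data.table(class = names(utab),
                             universe_count = as.integer(utab),
                             universe_proportion = as.numeric(utab) / length(universe)),
      by = "class", all = TRUE)
    for (col in c("count", "proportion", "universe_count", "universe_proportion"))
      out[[col]][is.na(out[[col]])] <- 0
  }
  list(table = out[order(-out$count)], peak_class = peak_class)
}

assign_largest_overlap_class <- function(peaks, repeats) {
  hits <- GenomicRanges::findOverlaps(peaks, repeats)
  cls <- rep("unannotated", length(peaks))
  if (length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(peaks)[S4Vectors::queryHits(hits)],
      IRanges::ranges(repeats)[S4Vectors::subjectHits(hits)]))
    dt <- data.table::data.table(
      peak = S4Vectors::queryHits(hits),
      class = S4Vectors::mcols(repeats)$class[S4Vectors::subjectHits(hits)],
      overlap = ov,
      ann_start = GenomicRanges::start(repeats)[S4Vectors::subjectHits(hits)])
    data.table::setorder(dt, peak, -overlap, ann_start)
    best <- dt[!duplicated(dt$peak)]
    cls[best$peak] <- best$class
  }
  cls
}

#' Bootstrap empirical enrichment p-value
#'
#' Compares an observed statistic against `n_sim` draws from a seeded null
#' sampler. The empirical p uses the add-one formula
#' `p = (1 + #extreme-or-equal) / (1 + n_sim)` (exact and conservative); the
#' full simulated vector is retained so the null density can be reported.
#'
#' @param observed Observed statistic.
#' @param sampler Zero-argument function returning one null draw; must be
#'   deterministic given the RNG state.
#' @param n_sim Number of simulations (default 10000).
#' @param direction `"greater"`, `"less"` or `"two_sided"` (doubles the
#'   smaller tail, capped at 1).
#' @param seed Integer seed.
#' @return List with `observed`, `simulated`, `p`, `direction`, `seed`.
#' @export
bootstrap_enrichment <- function(observed, sampler, n_sim = 10000,
                                 direction = c("greater", "less", "two_sided"),
                                 seed = 1) {
  direction <- match.arg(direction)
  if (n_sim < 1) stop("n_sim must be >= 1")
  sims <- with_seed(seed, vapply(seq_len(n_sim), function(i) sampler(),
                                 numeric(1)))
  p_greater <- (1 + sum(sims >= observed)) / (1 + n_sim)
  p_less <- (1 + sum(sims <= observed)) / (1 + n_sim)
  p <- switch(direction,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  ad_log("bootstrap_enrichment: observed %.4g, p = %.4g (%s, %d sims, seed %d)",
         observed, p, direction, n_sim, seed)
  list(observed = observed, simulated = sims, p = p, direction = direction,
       seed = seed)
}
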