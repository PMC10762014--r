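#' Poisson pairwise differential test
#'
#' Exact test comparing two Poisson counts with library-size normalization.
#' Two formulations are provided:
#'
#' * `"conditional"` (default): the exact conditional comparison of two
#'   Poisson rates. Under the null (rates proportional to library totals),
#'   conditional on `n = count_ref + count_obs` the observed count is
#'   `Binomial(n, total_obs / (total_ref + total_obs))`; tail sums of that
#'   distribution give the p-value. This form is correctly calibrated (it
#'   accounts for sampling noise in both counts), conservative only through
#'   discreteness, and exactly symmetric under swapping the two samples
#'   (increase and decrease tails exchange).
#' * `"rate"`: treats the normalized reference as a known rate,
#'   `lambda = (count_ref + pseudocount) * total_obs / total_ref`, and sums
#'   Poisson tails at `lambda`. This is the plug-in form (closed-form tails
#'   such as `P(X = 0) = exp(-lambda)`); it ignores reference noise and is
#'   anti-conservative for moderate counts, so the pipeline does not use it
#'   for calling.
#'
#' In both forms the two-sided p is `2 * min(p_increase, p_decrease, 0.5)`.
#' p-values depend on the totals only through their ratio (scaling
#' invariance). Vectorized over units.
#'
#' @param count_ref,count_obs Counts in the reference and observed samples
#'   (real-valued scaled counts are rounded to the nearest integer for the
#'   conditional form; the rate form rounds only `count_obs`).
#' @param total_ref,total_obs Library totals (reads or contacts), > 0.
#' @param direction `"increase"`, `"decrease"` or `"two_sided"`.
#' @param pseudocount Added to `count_ref` in the rate form only (default 1,
#'   guarding zero references; 0 gives the unmodified closed forms).
#' @param method `"conditional"` (default) or `"rate"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' poisson_pairwise_test(5, 0, 1, 1, "decrease", pseudocount = 0,
#'                       method = "rate")  # exp(-5)
#' poisson_pairwise_test(10, 30, 1e6, 1e6, "two_sided")
#' @export
poisson_pairwise_test <- function(count_ref, count_obs, total_ref, total_obs,
                                  direction = c("two_sided", "increase", "decrease"),
                                  pseudocount = 1,
                                  method = c("conditional", "rate")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (any(count_ref < 0) || any(count_obs < 0)) stop("counts must be >= 0")
  if (any(total_ref <= 0) || any(total_obs <= 0)) stop("totals must be > 0")
  if (method == "conditional") {
    a <- round(count_ref); b <- round(count_obs)
    n <- a + b
    t_obs <- total_obs / (total_ref + total_obs)
    p_inc <- stats::pbinom(b - 1, n, t_obs, lower.tail = FALSE)
    # P(X <= b) written as the upper tail of the complementary binomial so
    # that swapping the samples exchanges the two tails bit-for-bit
    p_dec <- stats::pbinom(a - 1, n, 1 - t_obs, lower.tail = FALSE)
  } else {
    lambda <- (count_ref + pseudocount) * (total_obs / total_ref)
    b <- round(count_obs)
    p_inc <- stats::ppois(b - 1, lambda, lower.tail = FALSE)
    p_dec <- stats::ppois(b, lambda, lower.tail = TRUE)
  }
  switch(direction,
         increase = p_inc,
         decrease = p_dec,
         two_sided = pmin(1, 2 * pmin(p_inc, p_dec, 0.5)))
}

#' One-tailed Fisher's exact test for enrichment
#'
#' Exact one-tailed p-value for enrichment of the observed sample on the 2x2
#' table `[count_obs, total_obs - count_obs; count_ref, total_ref - count_ref]`,
#' computed as the hypergeometric upper tail
#' `P(X >= count_obs)` with `X ~ Hypergeom(N = total_ref + total_obs,
#' K = count_ref + count_obs, n = total_obs)`. Vectorized.
#'
#' @param count_ref,count_obs Successes in each sample.
#' @param total_ref,total_obs Sample totals (counts must not exceed them).
#' @return Numeric vector of one-tailed p-values.
#' @export
fisher_increase_test <- function(count_ref, count_obs, total_ref, total_obs) {
  if (any(count_ref < 0) || any(count_obs < 0) ||
      any(total_ref - count_ref < 0) || any(total_obs - count_obs < 0))
    stop("all table cells must be >= 0")
  K <- count_ref + count_obs
  N <- total_ref + total_obs
  stats::phyper(count_obs - 1, K, N - K, total_obs, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; input order is
#' preserved. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Pseudocounted, library-normalized fold change (obs over ref).
fold_change <- function(count_ref, count_obs, total_ref, total_obs,
                        pseudocount = 1) {
  ((count_obs + pseudocount) / total_obs) /
    ((count_ref + pseudocount) / total_ref)
}

#' Tiered increased-peak calling
#'
#' Runs a one-tailed (increase) test per peak — Fisher's exact or the Poisson
#' pairwise test — adjusts across all peaks with BH, and assigns every peak
#' each tier whose q threshold it passes. Tiers are nested by construction
#' (`high` implies `medium` implies `low`).
#'
#' @param counts data.frame with columns `id`, `count_ref`, `count_obs`,
#'   `total_ref`, `total_obs` (one row per peak).
#' @param method `"fisher"` (default) or `"poisson"`.
#' @param tiers Named decreasing q thresholds; defaults
#'   `c(low = 5e-4, medium = 1e-5, high = 1e-7)`.
#' @param pseudocount Pseudocount for the Poisson rate and the fold change.
#' @return data.table with p, q, FC, `class` (`increased` if the loosest tier
#'   passes, else `unchanged`), one logical `tier_<name>` column per tier and
#'   a `tier` string of the passed tiers.
#' @export
call_increased_peaks <- function(counts,
                                 method = c("fisher", "poisson"),
                                 tiers = c(low = 5e-4, medium = 1e-5, high = 1e-7),
                                 pseudocount = 1) {
  method <- match.arg(method)
  if (nrow(counts) == 0) stop("empty peak list")
  if (is.unsorted(rev(tiers))) stop("tiers must be strictly decreasing")
  p <- if (method == "fisher") {
    fisher_increase_test(counts$count_ref, counts$count_obs,
                         counts$total_ref, counts$total_obs)
  } else {
    poisson_pairwise_test(counts$count_ref, counts$count_obs,
                          counts$total_ref, counts$total_obs,
                          direction = "increase", pseudocount = pseudocount)
  }
  q <- bh_adjust(p)
  fc <- fold_change(counts$count_ref, counts$count_obs,
                    counts$total_ref, counts$total_obs, pseudocount)
  out <- data.table::data.table(id = counts$id, count_ref = counts$count_ref,
                                count_obs = counts$count_obs,
                                p = p, q = q, FC = fc, method = method)
  passed <- matrix(FALSE, nrow(out), length(tiers),
                   dimnames = list(NULL, names(tiers)))
  for (tn in names(tiers)) {
    passed[, tn] <- q < tiers[[tn]]
    out[[paste0("tier_", tn)]] <- passed[, tn]
  }
  out$tier <- apply(passed, 1, function(z) paste(names(tiers)[z], collapse = ","))
  out$class <- ifelse(passed[, 1], "increased", "unchanged")
  ad_log("call_increased_peaks(%s): %d peaks, %s", method, nrow(out),
         paste(sprintf("%s=%d", names(tiers), colSums(passed)), collapse = " "))
  out
}

#' Dysregulated gene / repeat classification
#'
#' Two-sided Poisson pairwise test per feature, BH within the feature family,
#' then thresholding: `up` when `q < q_threshold` and `FC > fc_threshold`,
#' `down` when `q < q_threshold` and `FC < 1/fc_threshold`, otherwise
#' `unchanged`. The q threshold is 0.001 for genes and 0.01 for individual
#' repeats; the fold-change threshold is 2 for both.
#'
#' @param counts data.frame with columns `id`, `count_ref`, `count_obs`,
#'   `total_ref`, `total_obs`.
#' @param feature_kind `"gene"` or `"repeat"`.
#' @param pseudocount Pseudocount for rate and fold change.
#' @return data.table with p, q, FC and `class` in `{up, down, unchanged}`.
#' @export
call_dysregulated <- function(counts, feature_kind = c("gene", "repeat"),
                              pseudocount = 1) {
  feature_kind <- match.arg(feature_kind)
  q_threshold <- switch(feature_kind, gene = 0.001, "repeat" = 0.01)
  fc_threshold <- 2
  p <- poisson_pairwise_test(counts$count_ref, counts$count_obs,
                             counts$total_ref, counts$total_obs,
                             direction = "two_sided", pseudocount = pseudocount)
  q <- bh_adjust(p)
  fc <- fold_change(counts$count_ref, counts$count_obs,
                    counts$total_ref, counts$total_obs, pseudocount)
  class <- ifelse(q < q_threshold & fc > fc_threshold, "up",
                  ifelse(q < q_threshold & fc < 1 / fc_threshold, "down",
                         "unchanged"))
  ad_log("call_dysregulated(%s): %d features, %d up, %d down", feature_kind,
         nrow(counts), sum(class == "up"), sum(class == "down"))
  data.table::data.table(id = counts$id, count_ref = counts$count_ref,
                         count_obs = counts$count_obs, p = p, q = q, FC = fc,
                         class = class, kind = feature_kind)
}

#' Number-matched random feature control
#'
#' Draws `n` features uniformly without replacement from `universe` minus
#' `exclude`, deterministically under `seed`. Exclusion matches by exact
#' coordinates (chrom, start, end).
#'
#' @param universe `GRanges` feature set to sample from.
#' @param exclude `GRanges` features to remove from the universe first (may
#'   be NULL).
#' @param n Number of features to draw.
#' @param seed Integer seed.
#' @return A `GRanges` of `n` sampled features (input order of the eligible
#'   list is the sampling frame).
#' @export
sample_matched_random <- function(universe, exclude = NULL, n, seed) {
  key <- function(gr) paste(GenomicRanges::seqnames(gr),
                            GenomicRanges::start(gr),
                            GenomicRanges::end(gr), sep = ":")
  eligible <- if (is.null(exclude) || length(exclude) == 0) universe
              else universe[!(key(universe) %in% key(exclude))]
  if (length(eligible) < n)
    stop(sprintf("universe minus exclusions has %d features, need %d",
                 length(eligible), n))
  idx <- with_seed(seed, sample.int(length(eligible), n))
  ad_log("sample_matched_random: %d of %d eligible (seed %d)", n,
         length(eligible), seed)
  eligible[sort(idx)]
}
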