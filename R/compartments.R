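#' Observed/expected transformation of a contact map
#'
#' For each chromosome, the expected value at genomic distance `d` is the
#' mean of all matrix entries at that distance (zero cells included, no
#' smoothing, diagonal included); O/E is observed divided by expected, with
#' cells of zero expected masked as NA.
#'
#' @param cm A [contact_map()].
#' @return Named list per chromosome: `oe` (dense symmetric matrix),
#'   `expected` (per-distance means). Chromosomes with no contacts are
#'   skipped with a warning.
#' @export
observed_expected <- function(cm) {
  stopifnot(inherits(cm, "contact_map"))
  out <- list()
  for (chrom in names(cm$mats)) {
    if (sum(cm$mats[[chrom]]@x) == 0) {
      warning(sprintf("chromosome %s has no contacts; skipped", chrom))
      next
    }
    m <- dense_chrom(cm, chrom)
    n <- nrow(m)
    expected <- numeric(n)
    oe <- matrix(NA_real_, n, n)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      idx <- cbind(i, i + d)
      e <- mean(m[idx])
      expected[d + 1] <- e
      if (e > 0) {
        v <- m[idx] / e
        oe[idx] <- v
        oe[idx[, c(2, 1), drop = FALSE]] <- v
      }
    }
    out[[chrom]] <- list(oe = oe, expected = expected)
  }
  out
}

#' Leading eigenvectors of the O/E correlation matrix
#'
#' Drops masked bins (rows that are entirely NA or all-zero in the O/E
#' matrix), computes the Pearson correlation matrix of the remaining rows
#' (masked cells dropped pairwise), and returns the three unit-norm
#' eigenvectors of largest absolute eigenvalue, with masked bins reinserted
#' as NA.
#'
#' @param oe Dense O/E matrix for one chromosome (as from
#'   [observed_expected()]).
#' @param min_bins Minimum usable bins (default 10).
#' @return List with `vectors` (bins x 3, NA at masked bins), `values`
#'   (eigenvalues) and `used` (logical mask of usable bins).
#' @export
correlation_eigenvectors <- function(oe, min_bins = 10) {
  n <- nrow(oe)
  usable <- apply(oe, 1, function(r) {
    f <- r[is.finite(r)]
    length(f) > 1 && stats::sd(f) > 0
  })
  if (sum(usable) < min_bins)
    stop(sprintf("only %d usable bins (< %d)", sum(usable), min_bins))
  sub <- oe[usable, usable, drop = FALSE]
  cc <- if (anyNA(sub)) pairwise_pearson(sub) else stats::cor(sub)
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[1:3]
  vec <- matrix(NA_real_, n, 3)
  for (j in 1:3) {
    v <- eg$vectors[, ord[j]]
    vec[usable, j] <- v / sqrt(sum(v^2))
  }
  list(vectors = vec, values = eg$values[ord], used = usable)
}

# Pairwise-complete Pearson correlation of the columns of X, computed with
# masked cross-products (numerically equivalent to
# cor(X, use = "pairwise.complete.obs") but BLAS-speed on banded NA patterns).
pairwise_pearson <- function(X) {
  W <- is.finite(X) * 1
  X0 <- X; X0[!is.finite(X)] <- 0
  n <- crossprod(W)
  Sx <- crossprod(X0, W)     # sum of x_j over rows where x_k is present
  Sy <- t(Sx)
  Sxy <- crossprod(X0)
  Sxx <- crossprod(X0^2, W)
  Syy <- t(Sxx)
  cov <- Sxy / n - (Sx / n) * (Sy / n)
  vx <- Sxx / n - (Sx / n)^2
  vy <- Syy / n - (Sy / n)^2
  r <- cov / sqrt(vx * vy)
  r[n < 2 | !is.finite(r)] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' A/B compartment assignment
#'
#' For each chromosome, selects among the first three correlation
#' eigenvectors the one correlating best (largest |Pearson r|, ties to the
#' lowest index) with the accessibility (ATAC) signal on the same grid,
#' flips its sign if the correlation is negative, and labels bins A (score >
#' epsilon), B (score < -epsilon) or unclassified.
#'
#' @param eigs Named list per chromosome, each as returned by
#'   [correlation_eigenvectors()].
#' @param atac A [signal_track()] aggregated to the compartment bin size.
#' @param epsilon Dead zone around zero (default 0: every scored bin is
#'   labelled).
#' @return Object of class `compartment_profile`: data.table with chrom,
#'   bin (0-based), score, label, plus per-chromosome `chosen` index and
#'   `atac_r` attributes.
#' @export
assign_compartments <- function(eigs, atac, epsilon = 0) {
  stopifnot(inherits(atac, "signal_track"))
  rows <- list(); chosen <- integer(); atac_r <- numeric()
  for (chrom in names(eigs)) {
    vec <- eigs[[chrom]]$vectors
    a <- atac$values[[chrom]]
    if (length(a) != nrow(vec))
      stop(sprintf("ATAC grid mismatch on %s", chrom))
    if (stats::sd(a, na.rm = TRUE) == 0) {
      warning(sprintf("ATAC constant on %s; chromosome unclassified", chrom))
      rows[[chrom]] <- data.table::data.table(
        chrom = chrom, bin = seq_len(nrow(vec)) - 1L,
        score = NA_real_, label = "unclassified")
      chosen[chrom] <- NA_integer_; atac_r[chrom] <- NA_real_
      next
    }
    r <- vapply(1:3, function(j) {
      ok <- is.finite(vec[, j]) & is.finite(a)
      if (sum(ok) < 3 || stats::sd(vec[ok, j]) == 0) return(NA_real_)
      stats::cor(vec[ok, j], a[ok])
    }, numeric(1))
    j <- which.max(abs(r))  # ties resolve to the lowest index
    score <- vec[, j] * sign(r[j])
    label <- ifelse(!is.finite(score), "unclassified",
                    ifelse(score > epsilon, "A",
                           ifelse(score < -epsilon, "B", "unclassified")))
    rows[[chrom]] <- data.table::data.table(
      chrom = chrom, bin = seq_len(nrow(vec)) - 1L, score = score,
      label = label)
    chosen[chrom] <- j
    atac_r[chrom] <- abs(r[j])
    ad_log("assign_compartments %s: eigenvector %d, |r| = %.3f", chrom, j, abs(r[j]))
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "chosen", chosen)
  data.table::setattr(out, "atac_r", atac_r)
  data.table::setattr(out, "epsilon", epsilon)
  data.table::setattr(out, "class", c("compartment_profile", class(out)))
  out
}

#' Compartment switch classification
#'
#' Compares two compartment profiles on identical grids bin by bin. Label
#' pairs map to `A->B`, `B->A`, `unchanged`; any unclassified member makes
#' the bin unclassified. The switching fraction is reported over bins
#' classified in both profiles.
#'
#' @param wt,ko `compartment_profile` objects on the same grid.
#' @return Object of class `switch_table`: data.table with chrom, bin,
#'   score_wt, score_ko, class; attribute `switch_fraction`.
#' @export
classify_switching <- function(wt, ko) {
  if (!identical(wt$chrom, ko$chrom) || !identical(wt$bin, ko$bin))
    stop("compartment profiles are on different grids")
  lw <- wt$label; lk <- ko$label
  class <- ifelse(lw == "unclassified" | lk == "unclassified", "unclassified",
                  ifelse(lw == "A" & lk == "B", "A->B",
                         ifelse(lw == "B" & lk == "A", "B->A", "unchanged")))
  out <- data.table::data.table(chrom = wt$chrom, bin = wt$bin,
                                score_wt = wt$score, score_ko = ko$score,
                                class = class)
  classified <- class != "unclassified"
  frac <- if (any(classified)) mean(class[classified] != "unchanged") else NA_real_
  data.table::setattr(out, "switch_fraction", frac)
  data.table::setattr(out, "class", c("switch_table", class(out)))
  ad_log("classify_switching: %.2f%% of classified bins switch", 100 * frac)
  out
}

#' Switch-feature enrichment (two-tailed hypergeometric)
#'
#' Tests whether a feature bin set overlaps a switch bin set more (or less)
#' than expected under hypergeometric sampling from the universe.
#'
#' @param switch_bins,feature_bins Character or integer vectors of bin
#'   identifiers (subsets of `universe`).
#' @param universe All bins considered.
#' @return List with `k` (overlap), `p` (two-tailed, minimum-likelihood) and
#'   `fold` (`(k/n)/(K/N)`).
#' @export
switch_enrichment <- function(switch_bins, feature_bins, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(switch_bins %in% universe) || !all(feature_bins %in% universe))
    stop("switch and feature bins must be subsets of the universe")
  N <- length(universe); K <- length(switch_bins); n <- length(feature_bins)
  k <- length(intersect(feature_bins, switch_bins))
  p <- hypergeom_test(k, n, K, N, tail = "two_sided")
  fold <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
  list(k = k, n = n, K = K, N = N, p = p, fold = fold)
}
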