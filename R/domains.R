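#' Knight-Ruiz matrix balancing
#'
#' Balances each chromosome's contact matrix to uniform row sums with the
#' Knight-Ruiz inner-outer Newton iteration (conjugate-gradient inner solve).
#' Rows with zero marginal are masked before balancing and left zero. The
#' balanced matrix is `D M D` with the unmasked row sums equal to 1 within
#' `tol`; the per-bin scaling vector is returned (NA at masked bins).
#'
#' @param cm A [contact_map()] (raw counts).
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @param max_iter Maximum outer iterations (default 3000).
#' @return A balanced [contact_map()] with attribute `scaling` (named list
#'   of per-chromosome scaling vectors).
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(cm, "contact_map"))
  mats <- list(); scaling <- list()
  for (chrom in names(cm$mats)) {
    m <- dense_chrom(cm, chrom)
    marg <- rowSums(m)
    mask <- marg > 0
    x_full <- rep(NA_real_, nrow(m))
    bal <- matrix(0, nrow(m), ncol(m))
    if (sum(mask) >= 2) {
      sub <- m[mask, mask, drop = FALSE]
      x <- kr_core(sub, tol = tol, max_iter = max_iter, chrom = chrom)
      bal[mask, mask] <- sub * tcrossprod(x)
      x_full[mask] <- x
    }
    mats[[chrom]] <- to_upper_sparse(bal)
    scaling[[chrom]] <- x_full
  }
  out <- contact_map(mats, cm$bin_size, cm$layout, balanced = TRUE)
  attr(out, "scaling") <- scaling
  out
}

# Knight & Ruiz (2013) "bnewt" algorithm: outer Newton steps on the
# balancing fixed point, inner conjugate-gradient solves, with the published
# safeguarding bounds (delta, Delta) and adaptive inner tolerance.
kr_core <- function(A, tol = 1e-6, max_iter = 3000, delta = 0.1, Delta = 3,
                    chrom = "?") {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  outer_it <- 0
  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > max_iter)
      stop(sprintf(
        "KR balancing did not converge on %s: residual %.3g after %d outer iterations",
        chrom, sqrt(rout), max_iter))
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- NULL; p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > n) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # adaptive eta (forcing term) as in the published algorithm
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  ad_log("kr_balance %s: converged in %d outer iterations (residual %.3g)",
         chrom, outer_it, sqrt(rout))
  x
}

#' Directionality index
#'
#' For every bin, sums the contacts to bins within `window` upstream (`A`)
#' and downstream (`B`), truncated at chromosome ends, and scores the
#' up/downstream imbalance as
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)` with `E = (A + B)/2`;
#' `DI = 0` when `A + B = 0`. Positive DI marks downstream bias (domain
#' starts), negative upstream bias (domain ends).
#'
#' @param cm A [contact_map()], normally KR-balanced.
#' @param window Window in bp (a multiple of the bin size); default 2 Mb.
#' @return data.table (class `di_profile`) with chrom, bin (0-based), A, B,
#'   E, DI; attributes `window` and `bin_size`.
#' @export
directionality_index <- function(cm, window = 2e6) {
  stopifnot(inherits(cm, "contact_map"))
  if (window < cm$bin_size) stop("window must cover at least one bin")
  if (window %% cm$bin_size != 0) stop("window must be a multiple of bin size")
  w <- as.integer(window %/% cm$bin_size)
  rows <- lapply(names(cm$mats), function(chrom) {
    m <- dense_chrom(cm, chrom)
    n <- nrow(m)
    A <- numeric(n); B <- numeric(n)
    for (i in seq_len(n)) {
      up <- max(1L, i - w):(i - 1L)
      dn <- (i + 1L):min(n, i + w)
      if (i > 1L) A[i] <- sum(m[up, i])
      if (i < n) B[i] <- sum(m[i, dn])
    }
    E <- (A + B) / 2
    DI <- ifelse(A + B == 0, 0,
                 sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
    data.table::data.table(chrom = chrom, bin = seq_len(n) - 1L,
                           A = A, B = B, E = E, DI = DI)
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "window", window)
  data.table::setattr(out, "bin_size", cm$bin_size)
  data.table::setattr(out, "class", c("di_profile", class(out)))
  out
}

#' Simplified DI boundary caller
#'
#' A deterministic sign-transition scanner (not the original hidden-Markov
#' domain caller): a boundary is called at the first bin of every
#' `DI >= +threshold` run that follows a `DI <= -threshold` run, allowing
#' the two runs to be separated by at most one near-zero bin. The default
#' threshold is `0.4 * sd(|DI|)` over nonzero-DI bins, per chromosome.
#'
#' @param di A `di_profile` from [directionality_index()].
#' @param magnitude_threshold Numeric threshold; NULL (default) uses the
#'   per-chromosome adaptive rule.
#' @return data.table (class `boundary_set`) with chrom, bin (0-based,
#'   strictly increasing per chromosome).
#' @export
call_boundaries <- function(di, magnitude_threshold = NULL) {
  rows <- lapply(unique(di$chrom), function(chrom) {
    d <- di$DI[di$chrom == chrom]
    thr <- if (is.null(magnitude_threshold)) {
      nz <- abs(d[d != 0])
      if (length(nz) < 2) return(NULL)
      0.4 * stats::sd(nz)
    } else magnitude_threshold
    state <- ifelse(d >= thr, 1L, ifelse(d <= -thr, -1L, 0L))
    bounds <- integer()
    last_strong <- 0L; gap <- 0L
    for (i in seq_along(state)) {
      s <- state[i]
      if (s == 0L) {
        gap <- gap + 1L
      } else {
        if (s == 1L && last_strong == -1L && gap <= 1L)
          bounds <- c(bounds, i - 1L)  # 0-based: first bin of the positive run
        if (s != last_strong || gap > 1L) last_strong <- s
        gap <- 0L
      }
    }
    if (length(bounds) == 0) return(NULL)
    data.table::data.table(chrom = chrom, bin = bounds)
  })
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0)
    out <- data.table::data.table(chrom = character(), bin = integer())
  data.table::setattr(out, "class", c("boundary_set", class(out)))
  out
}

#' Merge boundary sets across samples
#'
#' Pools boundaries from several samples, unifies positions within
#' `tolerance_bins` of each other (merged position = midpoint of the cluster,
#' rounded down), and reports per-pair conservation: for each input set, the
#' fraction of its boundaries with a match in each other set.
#'
#' @param sets Named list of `boundary_set` tables.
#' @param tolerance_bins Maximum bin distance for unification (default 1).
#' @return List with `merged` (chrom, bin) and `conservation` (set_from,
#'   set_to, fraction_matched).
#' @export
merge_boundaries <- function(sets, tolerance_bins = 1) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("sample", seq_along(sets))
  pooled <- data.table::rbindlist(
    lapply(names(sets), function(s) {
      b <- sets[[s]]
      if (nrow(b) == 0) return(NULL)
      data.table::data.table(chrom = b$chrom, bin = b$bin, sample = s)
    }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(list(merged = data.table::data.table(chrom = character(), bin = integer()),
                conservation = data.table::data.table()))
  }
  data.table::setorder(pooled, chrom, bin)
  # greedy chaining: consecutive pooled boundaries within tolerance join a cluster
  cl <- integer(nrow(pooled)); cid <- 0L
  for (i in seq_len(nrow(pooled))) {
    if (i == 1 || pooled$chrom[i] != pooled$chrom[i - 1] ||
        pooled$bin[i] - pooled$bin[i - 1] > tolerance_bins) cid <- cid + 1L
    cl[i] <- cid
  }
  pooled$cluster <- cl
  merged <- pooled[, list(chrom = chrom[1],
                          bin = as.integer(floor((min(bin) + max(bin)) / 2))),
                   by = "cluster"][, c("chrom", "bin")]
  data.table::setorder(merged, chrom, bin)
  combos <- expand.grid(set_from = names(sets), set_to = names(sets),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$set_from != combos$set_to, , drop = FALSE]
  cons <- data.table::rbindlist(lapply(seq_len(nrow(combos)), function(i) {
    a <- sets[[combos$set_from[i]]]; b <- sets[[combos$set_to[i]]]
    frac <- if (nrow(a) == 0) NA_real_ else {
      mean(vapply(seq_len(nrow(a)), function(j) {
        any(b$chrom == a$chrom[j] & abs(b$bin - a$bin[j]) <= tolerance_bins)
      }, logical(1)))
    }
    data.table::data.table(set_from = combos$set_from[i],
                           set_to = combos$set_to[i],
                           fraction_matched = frac)
  }))
  list(merged = merged, conservation = cons)
}
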