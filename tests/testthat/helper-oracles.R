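# Independent oracles and tiny fixture builders shared across tests.
# Every oracle here is deliberately naive (enumeration, direct loops,
# textbook definitions) and never calls the implementation it checks.

toy_layout <- function(n_chrom = 2, len = 1e6) {
  genome_layout(sprintf("chr%d", seq_len(n_chrom)), rep(len, n_chrom))
}

# Textbook Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact hypergeometric pmf from binomial coefficients only.
hyper_pmf_oracle <- function(x, K, N, n) {
  choose(K, x) * choose(N - K, n - x) / choose(N, n)
}

# One-tailed Fisher enrichment p by summing the pmf over the tail.
fisher_oracle <- function(count_ref, count_obs, total_ref, total_obs) {
  K <- count_ref + count_obs
  N <- total_ref + total_obs
  support <- max(0, K - total_ref):min(total_obs, K)
  tail <- support[support >= count_obs]
  sum(hyper_pmf_oracle(tail, K, N, total_obs))
}

# Two-sided minimum-likelihood hypergeometric p by full enumeration.
hyper_two_sided_oracle <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  d <- hyper_pmf_oracle(support, K, N, n)
  dk <- hyper_pmf_oracle(k, K, N, n)
  sum(d[d <= dk * (1 + 1e-7)])
}

# Symmetric Sinkhorn-style balancing iteration (fixed point of
# d <- sqrt(d / (A d))), run to tight tolerance. Independent of kr_core.
sinkhorn_oracle <- function(A, tol = 1e-12, max_iter = 1e5) {
  d <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    r <- as.vector(A %*% d) * d
    if (max(abs(r - 1)) < tol) break
    d <- d * sqrt(1 / r)
  }
  d
}

# Build a contact_map from a dense symmetric matrix on one chromosome.
cm_from_dense <- function(m, bin_size = 1000, chrom_len = nrow(m) * 1000) {
  layout <- genome_layout("chr1", chrom_len)
  up <- m
  up[lower.tri(up)] <- 0
  contact_map(list(chr1 = Matrix::drop0(methods::as(up, "CsparseMatrix"))),
              bin_size, layout)
}

# Random sparse symmetric count matrix (dense storage).
random_contact_dense <- function(n, density = 0.3, max_count = 20) {
  m <- matrix(0, n, n)
  idx <- which(upper.tri(m, diag = TRUE))
  pick <- sample(idx, ceiling(length(idx) * density))
  m[pick] <- sample.int(max_count, length(pick), replace = TRUE)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# GRanges feature helper from vectors (0-based half-open coordinates).
gr_feats <- function(layout, chrom, start, end, name = NULL, class = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end)
  if (!is.null(name)) df$name <- name
  if (!is.null(class)) df$class <- class
  make_features(df, layout)
}
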