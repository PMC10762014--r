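#' Convert raw counts to RPKM
#'
#' Reads per kilobase per million mapped reads for every bin:
#' `RPKM = count / (bin_kb * library_total / 1e6)`.
#'
#' @param track A [signal_track()] in raw counts.
#' @param library_total Total mapped reads; defaults to the track's own
#'   `library_total`, falling back to the sum of all bins.
#' @return A [signal_track()] in RPKM units.
#' @export
counts_to_rpkm <- function(track, library_total = NULL) {
  stopifnot(inherits(track, "signal_track"))
  if (track$units != "count") stop("counts_to_rpkm expects a raw-count track")
  if (is.null(library_total)) {
    library_total <- if (!is.na(track$library_total)) track$library_total
                     else sum(vapply(track$values, sum, numeric(1)))
  }
  if (!is.finite(library_total) || library_total <= 0)
    stop("library_total must be > 0")
  denom <- (track$bin_size / 1000) * (library_total / 1e6)
  vals <- lapply(track$values, function(v) v / denom)
  signal_track(vals, track$bin_size, track$layout, units = "RPKM",
               library_total = library_total)
}

#' Subtract a matched input track
#'
#' Elementwise difference of two RPKM tracks on the same grid (ChIP minus
#' input). Negative values are retained, never clipped: they carry real
#' information about depletion relative to input.
#'
#' @param signal,input [signal_track()]s in RPKM on identical layouts.
#' @return A [signal_track()] in input-subtracted RPKM.
#' @export
input_subtract <- function(signal, input) {
  stopifnot(inherits(signal, "signal_track"), inherits(input, "signal_track"))
  if (signal$bin_size != input$bin_size) stop("bin sizes differ")
  if (!identical(names(signal$values), names(input$values)))
    stop("chromosome sets differ")
  vals <- Map(`-`, signal$values, input$values)
  signal_track(vals, signal$bin_size, signal$layout, units = "input_RPKM",
               library_total = signal$library_total)
}

#' Aggregate a track to larger windows
#'
#' Rebins a track to `window_size` (an exact multiple of the bin size) by
#' the mean (default) or sum of member bins. A trailing partial window uses
#' the bins available.
#'
#' @param track A [signal_track()].
#' @param window_size Window size in bp.
#' @param mode `"mean"` or `"sum"`.
#' @return A [signal_track()] at `window_size` bins (units preserved).
#' @export
aggregate_to_windows <- function(track, window_size, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "signal_track"))
  if (window_size %% track$bin_size != 0)
    stop("window_size must be an exact multiple of the track bin size")
  fac <- window_size %/% track$bin_size
  vals <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    grp <- (seq_along(v) - 1L) %/% fac
    s <- as.numeric(tapply(v, grp, if (mode == "sum") sum else mean))
    s
  })
  names(vals) <- names(track$values)
  signal_track(vals, window_size, track$layout, units = track$units,
               library_total = track$library_total)
}

#' Windows co-occupied by two marks
#'
#' Tiles the genome into fixed windows and returns exactly those windows that
#' overlap (by >= 1 bp) at least one peak of mark A from any sample AND at
#' least one peak of mark B from any sample. Optionally attaches per-sample
#' window mean signal columns.
#'
#' @param peaks_A,peaks_B Lists of `GRanges` peak sets (one per sample).
#' @param window_size Window size in bp.
#' @param layout A [genome_layout()].
#' @param tracks Optional named list of [signal_track()]s; each is
#'   mean-aggregated to the window grid and attached as a `signal_<name>`
#'   column.
#' @return data.table: chrom, start, end, `hasA_<i>`/`hasB_<i>` flags per
#'   sample and any signal columns; one row per co-occupied window.
#' @export
cooccupancy_windows <- function(peaks_A, peaks_B, window_size, layout,
                                tracks = NULL) {
  if (length(peaks_A) == 0 || length(peaks_B) == 0)
    stop("need at least one peak set per mark")
  tiles <- GenomicRanges::tileGenome(layout_seqinfo(layout),
                                     tilewidth = window_size,
                                     cut.last.tile.in.chrom = TRUE)
  flagsA <- vapply(peaks_A, function(p) GenomicRanges::countOverlaps(tiles, p) > 0,
                   logical(length(tiles)))
  flagsB <- vapply(peaks_B, function(p) GenomicRanges::countOverlaps(tiles, p) > 0,
                   logical(length(tiles)))
  flagsA <- matrix(flagsA, ncol = length(peaks_A))
  flagsB <- matrix(flagsB, ncol = length(peaks_B))
  keep <- rowSums(flagsA) > 0 & rowSums(flagsB) > 0
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(tiles))[keep],
    start = GenomicRanges::start(tiles)[keep] - 1L,
    end = GenomicRanges::end(tiles)[keep])
  for (s in seq_len(ncol(flagsA))) out[[paste0("hasA_", s)]] <- flagsA[keep, s]
  for (s in seq_len(ncol(flagsB))) out[[paste0("hasB_", s)]] <- flagsB[keep, s]
  if (!is.null(tracks)) {
    for (nm in names(tracks)) {
      agg <- aggregate_to_windows(tracks[[nm]], window_size, mode = "mean")
      win_idx <- out$start %/% window_size + 1L
      out[[paste0("signal_", nm)]] <-
        unlist(Map(function(chrom, i) agg$values[[chrom]][i],
                   out$chrom, win_idx), use.names = FALSE)
    }
  }
  ad_log("cooccupancy_windows: %d of %d windows co-occupied", nrow(out),
         length(tiles))
  out
}

#' Mutual-exclusivity summary of two window signal columns
#'
#' Summarizes the relationship between two marks over co-occupied windows:
#' the Pearson correlation of the two signals, and the fraction of windows
#' jointly above each signal's `high_quantile` (the "double-high fraction" —
#' near zero when the marks are mutually exclusive).
#'
#' @param table Window table from [cooccupancy_windows()].
#' @param sample_A,sample_B Names of the two signal columns.
#' @param high_quantile Quantile defining "high" signal (default 0.9).
#' @return List with `r`, `double_high_fraction`, `n_windows`,
#'   `high_quantile`. `r` is NA (with a warning) if a column is constant.
#' @export
exclusivity_summary <- function(table, sample_A, sample_B, high_quantile = 0.9) {
  stopifnot(sample_A %in% names(table), sample_B %in% names(table))
  a <- table[[sample_A]]; b <- table[[sample_B]]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant signal column: correlation undefined")
    NA_real_
  } else stats::cor(a, b)
  qa <- stats::quantile(a, high_quantile, names = FALSE)
  qb <- stats::quantile(b, high_quantile, names = FALSE)
  list(r = r, double_high_fraction = mean(a > qa & b > qb),
       n_windows = length(a), high_quantile = high_quantile)
}

#' Signal profile around anchor midpoints
#'
#' Extracts the track values at offsets `[-flank, +flank]` around the
#' midpoint bin of every anchor. Rows at chromosome edges are padded with NA
#' and excluded from the mean curve position-wise.
#'
#' @param track A [signal_track()].
#' @param anchors `GRanges` feature set; each anchor is represented by its
#'   midpoint.
#' @param flank Flank in bp; must be a multiple of the track bin size.
#' @return List with `matrix` (anchors x offsets), `offsets` (bp, bin
#'   midpoint-relative) and `mean_curve`.
#' @export
profile_around <- function(track, anchors, flank) {
  stopifnot(inherits(track, "signal_track"))
  if (flank %% track$bin_size != 0) stop("flank must be a multiple of bin size")
  k <- flank %/% track$bin_size
  dt <- features_to_dt(anchors)
  mid_bin <- ((dt$start + dt$end) %/% 2) %/% track$bin_size + 1L
  m <- matrix(NA_real_, nrow = nrow(dt), ncol = 2L * k + 1L)
  for (i in seq_len(nrow(dt))) {
    v <- track$values[[dt$chrom[i]]]
    idx <- (mid_bin[i] - k):(mid_bin[i] + k)
    valid <- idx >= 1L & idx <= length(v)
    m[i, valid] <- v[idx[valid]]
  }
  offsets <- seq(-k, k) * track$bin_size
  list(matrix = m, offsets = offsets,
       mean_curve = colMeans(m, na.rm = TRUE))
}

#' Sum of track values over feature intervals
#'
#' Sums the bins of a track covered by each feature (bins overlapping the
#' feature by >= 1 bp) — the count-extraction step behind every per-peak or
#' per-feature pairwise test on binned tracks.
#'
#' @param track A [signal_track()].
#' @param features `GRanges` feature set.
#' @return Numeric vector of per-feature sums.
#' @export
count_in_features <- function(track, features) {
  dt <- features_to_dt(features)
  out <- numeric(nrow(dt))
  for (chrom in unique(dt$chrom)) {
    v <- track$values[[chrom]]
    cs <- cumsum(c(0, v))
    sel <- which(dt$chrom == chrom)
    b0 <- dt$start[sel] %/% track$bin_size          # first covered bin
    b1 <- (dt$end[sel] - 1L) %/% track$bin_size     # last covered bin
    out[sel] <- cs[b1 + 2L] - cs[b0 + 1L]
  }
  out
}

#' Pooled CpG methylation in fixed windows
#'
#' Aggregates per-site methylation calls into fixed windows as the pooled
#' (count-weighted) ratio `sum(methylated) / sum(coverage)`. Windows whose
#' total aligned-read coverage is below `min_reads` are masked as NA.
#'
#' @param cpg_calls data.frame with columns `chrom`, `pos` (0-based),
#'   `coverage`, `methylated`.
#' @param layout A [genome_layout()].
#' @param window_size Window size in bp (default 100).
#' @param min_reads Minimum total coverage per window (default 5).
#' @return A [signal_track()] with units `"ratio"` (NA = masked).
#' @export
methylation_windows <- function(cpg_calls, layout, window_size = 100,
                                min_reads = 5) {
  stopifnot(all(c("chrom", "pos", "coverage", "methylated") %in% names(cpg_calls)))
  if (any(cpg_calls$methylated > cpg_calls$coverage))
    stop("methylated count exceeds coverage at some site")
  vals <- lapply(layout$chroms, function(chrom) {
    nb <- n_bins(layout, chrom, window_size)
    cov <- numeric(nb); met <- numeric(nb)
    sel <- cpg_calls$chrom == chrom
    if (any(sel)) {
      bin <- cpg_calls$pos[sel] %/% window_size + 1L
      cov_acc <- tapply(cpg_calls$coverage[sel], bin, sum)
      met_acc <- tapply(cpg_calls$methylated[sel], bin, sum)
      idx <- as.integer(names(cov_acc))
      cov[idx] <- as.numeric(cov_acc); met[idx] <- as.numeric(met_acc)
    }
    ratio <- ifelse(cov >= min_reads, met / cov, NA_real_)
    ratio
  })
  names(vals) <- layout$chroms
  signal_track(vals, window_size, layout, units = "ratio")
}

#' Seeded k-means row clustering
#'
#' Clusters rows of a signal matrix with k-means using a seeded k-means++
#' initialization (greedy D^2 sampling) followed by Lloyd iterations, so the
#' same seed always yields the same labels.
#'
#' @param mat Numeric matrix (rows = units, columns = samples).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations (default 100).
#' @return List with `labels` (per input row), `order` (row indices grouped
#'   by cluster) and `centers`.
#' @export
cluster_rows <- function(mat, k, seed, iter_max = 100) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("matrix must be finite")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  if (k == 1) {
    labels <- rep(1L, nrow(mat))
    return(list(labels = labels, order = seq_len(nrow(mat)),
                centers = matrix(colMeans(mat), nrow = 1)))
  }
  centers <- with_seed(seed, kmeanspp_init(mat, k))
  fit <- suppressWarnings(
    stats::kmeans(mat, centers = centers, iter.max = iter_max,
                  algorithm = "Lloyd"))
  labels <- fit$cluster
  list(labels = labels, order = order(labels), centers = fit$centers)
}

# k-means++ D^2-weighted seeding (Arthur & Vassilvitskii)
kmeanspp_init <- function(mat, k) {
  n <- nrow(mat)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(mat))
  first <- sample.int(n, 1)
  centers[1, ] <- mat[first, ]
  d2 <- rowSums(sweep(mat, 2, centers[1, ])^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    pick <- sample.int(n, 1, prob = probs)
    centers[j, ] <- mat[pick, ]
    d2 <- pmin(d2, rowSums(sweep(mat, 2, centers[j, ])^2))
  }
  # nudge exact duplicates so stats::kmeans accepts the centers
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] + 1e-9
  centers
}
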