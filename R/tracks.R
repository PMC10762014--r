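#' Binned signal track
#'
#' Dense per-chromosome arrays of binned values — the unit of all 1-D
#' quantification. Raw counts must be non-negative; input-subtracted values
#' may be negative and are never clipped.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin size in bp.
#' @param layout A [genome_layout()]; array lengths must equal
#'   `ceiling(length / bin_size)`.
#' @param units One of `"count"`, `"RPKM"`, `"input_RPKM"`, `"RPM"`,
#'   `"normalized"`, `"ratio"`.
#' @param library_total Total mapped reads (required for RPKM/RPM conversion).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, layout,
                         units = c("count", "RPKM", "input_RPKM", "RPM",
                                   "normalized", "ratio"),
                         library_total = NA_real_) {
  units <- match.arg(units)
  stopifnot(inherits(layout, "genome_layout"),
            all(names(values) %in% layout$chroms))
  for (chrom in names(values)) {
    nb <- n_bins(layout, chrom, bin_size)
    if (length(values[[chrom]]) != nb) {
      stop(sprintf("track on %s: %d bins, expected %d",
                   chrom, length(values[[chrom]]), nb))
    }
  }
  if (units == "count" && any(vapply(values, function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stop("raw counts must be >= 0")
  structure(list(values = values, bin_size = bin_size, layout = layout,
                 units = units, library_total = library_total),
            class = "signal_track")
}

#' @exportS3Method base::print
#' @noRd
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> bin %d bp, units %s, %d chromosome(s)\n",
              as.integer(x$bin_size), x$units, length(x$values)))
  invisible(x)
}

#' Sparse binned contact map
#'
#' Per-chromosome intra-chromosomal contact matrices stored upper-triangular
#' (row index <= column index, 1-based over bins of `bin_size`). The total is
#' the sum of all stored entries with the diagonal counted once.
#'
#' @param mats Named list of `Matrix::sparseMatrix` objects (square,
#'   upper-triangular), one per chromosome.
#' @param bin_size Bin size in bp.
#' @param layout A [genome_layout()].
#' @param balanced Logical; whether values are balanced (normalized) rather
#'   than raw counts.
#' @return An object of class `contact_map` with element `total`.
#' @export
contact_map <- function(mats, bin_size, layout, balanced = FALSE) {
  stopifnot(inherits(layout, "genome_layout"),
            all(names(mats) %in% layout$chroms))
  for (chrom in names(mats)) {
    nb <- n_bins(layout, chrom, bin_size)
    m <- mats[[chrom]]
    if (nrow(m) != nb || ncol(m) != nb)
      stop(sprintf("contact matrix on %s: %dx%d, expected %d bins",
                   chrom, nrow(m), ncol(m), nb))
    if (any(m@x < 0)) stop(sprintf("negative contact count on %s", chrom))
  }
  structure(list(mats = mats, bin_size = bin_size, layout = layout,
                 balanced = balanced,
                 total = sum(vapply(mats, function(m) sum(m@x), numeric(1)))),
            class = "contact_map")
}

#' @exportS3Method base::print
#' @noRd
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> bin %d bp, %d chromosome(s), total %.4g contacts%s\n",
              as.integer(x$bin_size), length(x$mats), x$total,
              if (x$balanced) " (balanced)" else ""))
  invisible(x)
}

# Dense symmetric matrix for one chromosome of a contact map.
dense_chrom <- function(cm, chrom) {
  m <- as.matrix(cm$mats[[chrom]])
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

# Dense symmetric matrix -> sparse upper-triangular storage.
to_upper_sparse <- function(m) {
  m[lower.tri(m)] <- 0
  Matrix::drop0(methods::as(m, "CsparseMatrix"))
}
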