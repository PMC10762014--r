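#' Genome layout
#'
#' A minimal description of the genome the pipeline operates on: chromosome
#' names and lengths. All interval and bin coordinates elsewhere are validated
#' against a layout. Coordinates follow the BED convention (0-based,
#' half-open); bin `i` at bin size `w` covers `[i*w, (i+1)*w)`.
#'
#' @param chroms Character vector of chromosome names.
#' @param lengths Numeric vector of chromosome lengths in base pairs.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms))
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(list(chroms = as.character(chroms),
                 lengths = stats::setNames(lengths, chroms)),
            class = "genome_layout")
}

#' @exportS3Method base::print
#' @noRd
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %.3g Mb total\n",
              length(x$chroms), sum(x$lengths) / 1e6))
  invisible(x)
}

#' Number of bins on a chromosome at a given bin size
#' @param layout A [genome_layout()].
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @return Integer bin count (`ceiling(length / bin_size)`).
#' @export
n_bins <- function(layout, chrom, bin_size) {
  stopifnot(inherits(layout, "genome_layout"), chrom %in% layout$chroms)
  as.integer(ceiling(layout$lengths[[chrom]] / bin_size))
}

#' Convert a layout to a Seqinfo object
#' @param layout A [genome_layout()].
#' @return A [GenomeInfoDb::Seqinfo] for use in GRanges construction.
#' @keywords internal
layout_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout$chroms,
                        seqlengths = as.integer(layout$lengths))
}

#' Build a feature set (GRanges) from a coordinate table
#'
#' Features are plain genomic intervals with optional `name`, `score` and
#' `class` metadata; they are stored as a `GRanges` on the layout's seqinfo.
#' Strand is ignored throughout the pipeline.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `class`.
#' @param layout A [genome_layout()]; intervals are validated against it.
#' @return A `GRanges` with mcols `name` (always set), and `score`/`class`
#'   when supplied.
#' @export
make_features <- function(df, layout) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  validate_intervals(df, layout)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqinfo = layout_seqinfo(layout))
  nm <- if (!is.null(df$name) && !all(is.na(df$name))) as.character(df$name)
        else sprintf("feat_%d", seq_len(nrow(df)))
  S4Vectors::mcols(gr)$name <- nm
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  if (!is.null(df$class)) S4Vectors::mcols(gr)$class <- as.character(df$class)
  gr
}

# Validate BED-convention intervals against a layout; errors carry the
# offending row index.
validate_intervals <- function(df, layout) {
  bad_chrom <- !(df$chrom %in% layout$chroms)
  if (any(bad_chrom)) {
    stop(sprintf("interval %d: unknown chromosome '%s'",
                 which(bad_chrom)[1], df$chrom[which(bad_chrom)[1]]))
  }
  len <- layout$lengths[df$chrom]
  bad <- df$start < 0 | df$start >= df$end | df$end > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("interval %d (%s:%s-%s): violates 0 <= start < end <= chrom length",
                 i, df$chrom[i], format(df$start[i], scientific = FALSE),
                 format(df$end[i], scientific = FALSE)))
  }
  invisible(TRUE)
}

# GRanges -> plain 0-based coordinate data.table
features_to_dt <- function(gr) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  for (col in colnames(mc)) dt[[col]] <- mc[[col]]
  dt
}
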