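#' Read genomic intervals (BED / BED-like)
#'
#' Parses 3+ column tab-separated BED text into a feature set. Columns beyond
#' the first three are interpreted as `name`, `score`, `class` in order.
#' Input order is preserved and stable identifiers (`feat_<i>`) are assigned
#' when the name column is absent. No record is silently dropped: malformed
#' lines and intervals outside the layout raise errors naming the line.
#'
#' @param path BED file path.
#' @param layout A [genome_layout()].
#' @return A `GRanges` feature set (see [make_features()]).
#' @export
read_intervals <- function(path, layout) {
  dt <- read_tab(path, min_cols = 3)
  if (nrow(dt) == 0) return(make_features(
    data.frame(chrom = character(), start = numeric(), end = numeric()), layout))
  out <- data.table::data.table(chrom = as.character(dt[[1]]),
                                start = parse_num(dt[[2]], path, "start"),
                                end = parse_num(dt[[3]], path, "end"))
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- suppressWarnings(as.numeric(dt[[5]]))
  if (ncol(dt) >= 6) out$class <- as.character(dt[[6]])
  ad_log("read_intervals: %d records from %s", nrow(out), path)
  make_features(as.data.frame(out), layout)
}

#' Write a feature set as BED
#' @param features `GRanges` feature set.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(features, path) {
  dt <- features_to_dt(features)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "class"), names(dt))
  # BED columns are positional: fill gaps so later columns stay in place
  if ("class" %in% cols && !"score" %in% cols) dt$score <- 0
  if (("score" %in% names(dt) || "class" %in% cols) && !"name" %in% cols)
    dt$name <- sprintf("feat_%d", seq_len(nrow(dt)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "class"), names(dt))
  data.table::fwrite(dt[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read anchor pairs (BEDPE)
#'
#' Reads loop/interaction anchor pairs. Anchors are genome-ordered within
#' each pair (anchor1 precedes anchor2); the resolution is inferred from the
#' anchor width. Inter-chromosomal pairs are rejected with a warning (all
#' downstream analyses are intra-chromosomal). Duplicate records are
#' retained — merging is a separate operation.
#'
#' @param path BEDPE file path (chrom1,start1,end1,chrom2,start2,end2,...).
#' @param layout A [genome_layout()].
#' @return data.table with columns chrom, start1, end1, start2, end2,
#'   resolution, name.
#' @export
read_pairs <- function(path, layout) {
  dt <- read_tab(path, min_cols = 6)
  if (nrow(dt) == 0) {
    return(data.table::data.table(chrom = character(), start1 = numeric(),
                                  end1 = numeric(), start2 = numeric(),
                                  end2 = numeric(), resolution = numeric(),
                                  name = character()))
  }
  p <- data.table::data.table(
    chrom1 = as.character(dt[[1]]), start1 = parse_num(dt[[2]], path, "start1"),
    end1 = parse_num(dt[[3]], path, "end1"),
    chrom2 = as.character(dt[[4]]), start2 = parse_num(dt[[5]], path, "start2"),
    end2 = parse_num(dt[[6]], path, "end2"))
  p$name <- if (ncol(dt) >= 7) as.character(dt[[7]]) else sprintf("pair_%d", seq_len(nrow(p)))
  inter <- p$chrom1 != p$chrom2
  if (any(inter)) {
    warning(sprintf("rejected %d inter-chromosomal pair(s)", sum(inter)))
    p <- p[!inter]
  }
  ad_log("read_pairs: %d intra-chromosomal records from %s", nrow(p), path)
  if (nrow(p) == 0) return(read_pairs_empty())
  # canonical order: anchor1 before anchor2 on the genome
  swap <- p$start2 < p$start1
  if (any(swap)) {
    tmp_s <- p$start1[swap]; tmp_e <- p$end1[swap]
    p$start1[swap] <- p$start2[swap]; p$end1[swap] <- p$end2[swap]
    p$start2[swap] <- tmp_s; p$end2[swap] <- tmp_e
  }
  validate_intervals(data.frame(chrom = p$chrom1, start = p$start1, end = p$end1), layout)
  validate_intervals(data.frame(chrom = p$chrom1, start = p$start2, end = p$end2), layout)
  out <- p[, list(chrom = chrom1, start1, end1, start2, end2,
                  resolution = end1 - start1, name)]
  out
}

read_pairs_empty <- function() {
  data.table::data.table(chrom = character(), start1 = numeric(),
                         end1 = numeric(), start2 = numeric(),
                         end2 = numeric(), resolution = numeric(),
                         name = character())
}

#' Write anchor pairs as BEDPE
#' @param pairs data.table as returned by [read_pairs()]; extra columns are
#'   appended after the sixth BEDPE field.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  base <- data.table::data.table(
    chrom1 = pairs$chrom, start1 = pairs$start1, end1 = pairs$end1,
    chrom2 = pairs$chrom, start2 = pairs$start2, end2 = pairs$end2)
  extra <- setdiff(names(pairs), c("chrom", "start1", "end1", "start2", "end2", "resolution"))
  for (col in extra) base[[col]] <- pairs[[col]]
  data.table::fwrite(base, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binned signal track (bedGraph)
#'
#' Reads bedGraph records into a dense per-chromosome array at `bin_size`.
#' Records must align to the bin grid, or be exact subdivisions of it, in
#' which case they are aggregated on read: each bin's value is the
#' width-weighted sum of its source records divided by the bin size, i.e. the
#' mean over source bins with missing sub-intervals contributing zero.
#' Missing bins are zero.
#'
#' @param path bedGraph file path.
#' @param layout A [genome_layout()].
#' @param bin_size Target bin size in bp.
#' @param units Units to record on the track (default `"count"` is not
#'   assumed; use `"normalized"` for generic values).
#' @param library_total Optional library total to carry.
#' @return A [signal_track()].
#' @export
read_track <- function(path, layout, bin_size, units = "normalized",
                       library_total = NA_real_) {
  dt <- read_tab(path, min_cols = 4, allow_empty = TRUE)
  values <- lapply(layout$chroms, function(chrom)
    numeric(n_bins(layout, chrom, bin_size)))
  names(values) <- layout$chroms
  if (nrow(dt) > 0) {
    rec <- data.table::data.table(chrom = as.character(dt[[1]]),
                                  start = parse_num(dt[[2]], path, "start"),
                                  end = parse_num(dt[[3]], path, "end"),
                                  value = parse_num(dt[[4]], path, "value"))
    validate_intervals(rec, layout)
    first_bin <- rec$start %/% bin_size
    last_bin <- (rec$end - 1L) %/% bin_size
    multi <- first_bin != last_bin
    aligned <- rec$start %% bin_size == 0 &
      (rec$end %% bin_size == 0 | rec$end == layout$lengths[rec$chrom])
    bad <- multi & !aligned
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("record %d (%s:%s-%s) does not align to the %d bp bin grid",
                   i, rec$chrom[i], format(rec$start[i], scientific = FALSE),
                   format(rec$end[i], scientific = FALSE), as.integer(bin_size)))
    }
    for (chrom in unique(rec$chrom)) {
      sel <- rec$chrom == chrom
      v <- values[[chrom]]
      # width-weighted accumulation: exact for grid-aligned records, mean
      # (with absent sub-bins as 0) for subdivided ones
      r <- rec[sel]
      fb <- first_bin[sel]; lb <- last_bin[sel]
      one <- fb == lb
      if (any(one)) {
        w <- (r$end[one] - r$start[one]) / bin_size
        acc <- tapply(r$value[one] * w, fb[one], sum)
        idx <- as.integer(names(acc)) + 1L
        v[idx] <- v[idx] + as.numeric(acc)
      }
      for (i in which(!one)) {
        bins <- (fb[i]:lb[i]) + 1L
        v[bins] <- v[bins] + r$value[i]
      }
      values[[chrom]] <- v
    }
  }
  ad_log("read_track: %d records -> %d bp bins from %s", nrow(dt),
         as.integer(bin_size), path)
  signal_track(values, bin_size, layout, units = units,
               library_total = library_total)
}

#' Write a signal track as bedGraph
#'
#' Zero bins are omitted (bedGraph treats missing intervals as zero); NA bins
#' are omitted as well.
#'
#' @param track A [signal_track()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path) {
  parts <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    keep <- which(!is.na(v) & v != 0)
    if (length(keep) == 0) return(NULL)
    len <- track$layout$lengths[[chrom]]
    data.table::data.table(chrom = chrom,
                           start = (keep - 1) * track$bin_size,
                           end = pmin(keep * track$bin_size, len),
                           value = v[keep])
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0) {
    file.create(path)
  } else {
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a sparse contact map (text COO triples)
#'
#' The on-disk contract is plain text with four tab-separated columns:
#' `chrom`, `bin_i`, `bin_j`, `count`, with `bin_i <= bin_j` (0-based bin
#' indices at `bin_size`). Duplicate triples for one cell are summed.
#'
#' @param path COO file path.
#' @param layout A [genome_layout()].
#' @param bin_size Bin size in bp.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, layout, bin_size) {
  dt <- read_tab(path, min_cols = 4, allow_empty = TRUE)
  mats <- stats::setNames(vector("list", length(layout$chroms)), layout$chroms)
  if (nrow(dt) > 0) {
    rec <- data.table::data.table(chrom = as.character(dt[[1]]),
                                  i = parse_num(dt[[2]], path, "bin_i"),
                                  j = parse_num(dt[[3]], path, "bin_j"),
                                  count = parse_num(dt[[4]], path, "count"))
    if (any(rec$count < 0)) {
      k <- which(rec$count < 0)[1]
      stop(sprintf("record %d: negative contact count %s", k, rec$count[k]))
    }
    if (any(rec$i > rec$j)) stop("contact triples must satisfy bin_i <= bin_j")
    bad_chrom <- !(rec$chrom %in% layout$chroms)
    if (any(bad_chrom))
      stop(sprintf("record %d: unknown chromosome '%s'",
                   which(bad_chrom)[1], rec$chrom[which(bad_chrom)[1]]))
  }
  for (chrom in layout$chroms) {
    nb <- n_bins(layout, chrom, bin_size)
    if (nrow(dt) > 0 && any(rec$chrom == chrom)) {
      sel_rows <- which(rec$chrom == chrom)
      r <- rec[sel_rows]
      if (any(r$i < 0 | r$j >= nb)) {
        k <- which(r$i < 0 | r$j >= nb)[1]
        stop(sprintf("bin index out of range on %s: (%d, %d), %d bins",
                     chrom, as.integer(r$i[k]), as.integer(r$j[k]), nb))
      }
      mats[[chrom]] <- Matrix::sparseMatrix(i = r$i + 1L, j = r$j + 1L,
                                            x = r$count, dims = c(nb, nb))
    } else {
      mats[[chrom]] <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                            x = numeric(), dims = c(nb, nb))
    }
  }
  ad_log("read_contacts: %d triples from %s", nrow(dt), path)
  contact_map(mats, bin_size, layout)
}

#' Write a contact map as text COO triples
#' @param cm A [contact_map()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contacts <- function(cm, path) {
  parts <- lapply(names(cm$mats), function(chrom) {
    m <- methods::as(cm$mats[[chrom]], "TsparseMatrix")
    if (length(m@x) == 0) return(NULL)
    o <- order(m@i, m@j)
    data.table::data.table(chrom = chrom, i = m@i[o], j = m@j[o], count = m@x[o])
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0) file.create(path)
  else data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# fread wrapper: tab-separated, no header, errors mention the file; enforces
# a minimum column count so truncated lines fail loudly (fill = FALSE).
read_tab <- function(path, min_cols, allow_empty = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    if (allow_empty) return(data.table::data.table())
    stop(sprintf("empty file: %s", path))
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE,
                      colClasses = "character", data.table = TRUE),
    error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e))))
  if (nrow(dt) > 0 && ncol(dt) < min_cols)
    stop(sprintf("%s: expected >= %d tab-separated columns, found %d",
                 path, min_cols, ncol(dt)))
  dt
}

parse_num <- function(x, path, field) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    i <- which(is.na(v))[1]
    stop(sprintf("%s line %d: non-numeric %s field '%s'", path, i, field, x[i]))
  }
  v
}
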