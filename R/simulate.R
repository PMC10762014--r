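#' Simulation configuration
#'
#' Defaults encode the paired-condition study design the pipeline targets:
#' two 50 Mb chromosomes; 5,000 CTCF peak sites of which 200 gain binding
#' 4-fold in the knockout with reciprocal H3K9me3 loss (coupling 1); 1,000
#' genes and 2,000 classed repeats with planted 4-fold dysregulation;
#' 25 kb contact maps with power-law distance decay (alpha = 1), a
#' compartment checkerboard (same-compartment contrast 1.6x, cross 0.6x),
#' TAD blocks (11 per chromosome, 20 internal boundaries genome-wide) and
#' 500 loop spikes of which 50 intensify 3-fold in the knockout; 20 planted
#' compartment switch blocks of 10 bins.
#'
#' @param ... Named overrides of any default.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # genome
    n_chrom = 2, chrom_length = 50e6,
    # 1-D tracks
    chip_bin = 100, peak_width = 500, k9_width = 2000, site_slot = 5000,
    n_peaks = 5000, n_gain = 200, gain_ratio = 4, coupling = 1,
    n_cooccur_ctcf = 400, n_cooccur_k9 = 400, n_k9_only = 1000,
    peak_height = 20, k9_height = 16, weak_height = 1, background_rate = 0.2,
    atac_a_rate = 2, atac_b_rate = 0.5,
    # genes / repeats / expression
    n_genes = 1000, gene_width = 5000,
    n_genes_up = 60, n_genes_down = 40, gene_fc = 4,
    gene_base_rate = 100, gene_rate_sdlog = 0.6,
    switch_gene_coupling = 0.4,
    n_repeats = 2000, repeat_width = 200,
    repeat_classes = c(SINE_B2 = 0.35, SINE_Alu = 0.15, SINE_B4 = 0.10,
                       ERVL_MaLR = 0.10, LINE_L1 = 0.20, ERVK = 0.10),
    n_repeats_up = 120, n_repeats_down = 60, repeat_fc = 4,
    repeat_base_rate = 30, repeat_rate_sdlog = 0.6,
    gained_b2_fraction = 0.42, peak_repeat_overlap = 0.10,
    # contact maps
    hic_bin = 25000, hic_depth = 60, decay_alpha = 1.0,
    comp_block_bins = 20, comp_same = 1.6, comp_diff = 0.6,
    n_switch_blocks = 20, switch_block_bins = 10,
    n_tads_per_chrom = 11, tad_boost = 2.0,
    n_loops = 500, loop_strength = 20,
    n_loop_gain = 50, n_loop_loss = 0, loop_change_ratio = 3,
    loop_min_dist_bins = 4, loop_max_dist_bins = 40,
    interaction_res = c(25000, 10000, 5000),
    interaction_res_frac = c(1, 0.6, 0.4),
    n_bg_interactions = 200,
    overdispersion = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

#' Null (all-effects-one) configuration
#'
#' The default configuration with every planted effect switched off:
#' gain/loss ratios 1, no compartment switches, no dysregulated features.
#' Used for false-discovery calibration.
#'
#' @param ... Further overrides applied on top.
#' @return A `sim_config`.
#' @export
sim_config_null <- function(...) {
  sim_config(gain_ratio = 1, gene_fc = 1, repeat_fc = 1,
             n_genes_up = 0, n_genes_down = 0,
             n_repeats_up = 0, n_repeats_down = 0,
             loop_change_ratio = 1, n_loop_gain = 0, n_loop_loss = 0,
             n_switch_blocks = 0, ...)
}

# Poisson or (with overdispersion phi > 0) gamma-mixed Poisson draws.
rpois_od <- function(n, lambda, phi = 0) {
  if (phi <= 0) return(stats::rpois(n, lambda))
  shape <- 1 / phi
  stats::rpois(n, lambda * stats::rgamma(n, shape = shape, rate = shape))
}

#' Generate the genome and planted truth
#'
#' Builds the genome layout, gene and repeat annotations (exact configured
#' class counts), CTCF/H3K9me3 site placement with co-occupancy categories,
#' planted gained peaks, compartment blocks with planted switches, TAD
#' boundaries, loop positions with planted intensity changes, and expression
#' base rates with planted fold changes — everything downstream stages are
#' measured against. Deterministic under `seed`.
#'
#' Sites are placed one per 5 kb slot so no two sites share an aggregation
#' window; genes are non-overlapping by construction (packing failures are
#' an error). A configurable fraction of upregulated genes is placed inside
#' B-to-A switch blocks, emulating direct targets.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_truth`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(seed, "genome"), build_truth(config, seed))
}

build_truth <- function(cfg, seed) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  layout <- genome_layout(chroms, rep(cfg$chrom_length, cfg$n_chrom))

  ## --- compartments, switches, TADs, loops (25 kb grid) ---
  nb <- as.integer(cfg$chrom_length %/% cfg$hic_bin)
  comp <- list(); switch_blocks <- list(); tadb <- list(); loops <- list()
  n_switch_per_chrom <- diff(round(seq(0, cfg$n_switch_blocks,
                                       length.out = cfg$n_chrom + 1)))
  n_loop_per_chrom <- diff(round(seq(0, cfg$n_loops,
                                     length.out = cfg$n_chrom + 1)))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    wt_label <- rep(c("A", "B"), length.out = ceiling(nb / cfg$comp_block_bins))
    wt_label <- rep(wt_label, each = cfg$comp_block_bins)[seq_len(nb)]
    ko_label <- wt_label
    # planted switch blocks: aligned half-block windows of uniform WT label
    sw <- data.table::data.table()
    if (n_switch_per_chrom[ci] > 0) {
      half <- cfg$switch_block_bins
      starts_all <- seq(0, nb - half, by = half)
      uniform <- vapply(starts_all, function(s)
        length(unique(wt_label[(s + 1):(s + half)])) == 1, logical(1))
      cand <- starts_all[uniform]
      if (n_switch_per_chrom[ci] > length(cand))
        stop("infeasible packing: too many switch blocks for the chromosome")
      pick <- sort(cand[sample.int(length(cand), n_switch_per_chrom[ci])])
      sw <- data.table::data.table(
        chrom = chrom, start_bin = pick, end_bin = pick + half,
        direction = ifelse(wt_label[pick + 1] == "A", "A->B", "B->A"))
      for (r in seq_len(nrow(sw))) {
        idx <- (sw$start_bin[r] + 1):sw$end_bin[r]
        ko_label[idx] <- ifelse(wt_label[idx] == "A", "B", "A")
      }
    }
    comp[[chrom]] <- data.table::data.table(chrom = chrom, bin = 0:(nb - 1),
                                            wt_label = wt_label,
                                            ko_label = ko_label)
    switch_blocks[[chrom]] <- sw
    # TADs: partition the chromosome into n_tads blocks of >= 50 bins
    n_tads <- cfg$n_tads_per_chrom
    min_sz <- 50
    if (nb < n_tads * min_sz)
      stop("infeasible packing: too many TADs for the chromosome length")
    raw <- stats::runif(n_tads)
    sizes <- min_sz + floor((nb - n_tads * min_sz) * raw / sum(raw))
    sizes[n_tads] <- nb - sum(sizes[-n_tads])
    bounds <- cumsum(sizes)[-n_tads]  # 0-based first bin of each new TAD
    tadb[[chrom]] <- data.table::data.table(chrom = chrom, bin = as.integer(bounds))
    # loops: unique (bin1, bin2) cells at mid-range distances
    nl <- n_loop_per_chrom[ci]
    b1 <- integer(0); b2 <- integer(0)
    while (length(b1) < nl) {
      need <- nl - length(b1)
      d <- sample(cfg$loop_min_dist_bins:cfg$loop_max_dist_bins, need * 2,
                  replace = TRUE)
      i <- sample.int(nb - max(d), need * 2, replace = TRUE)
      j <- i + d
      dup <- duplicated(c(paste(b1, b2), paste(i, j)))
      keep <- !dup[length(b1) + seq_along(i)]
      b1 <- c(b1, i[keep]); b2 <- c(b2, j[keep])
      b1 <- b1[seq_len(min(nl, length(b1)))]
      b2 <- b2[seq_len(length(b1))]
    }
    loops[[chrom]] <- data.table::data.table(chrom = chrom,
                                             bin1 = b1 - 1L, bin2 = b2 - 1L)
  }
  comp <- data.table::rbindlist(comp)
  switch_blocks <- data.table::rbindlist(switch_blocks)
  tad_boundaries <- data.table::rbindlist(tadb)
  loops <- data.table::rbindlist(loops)
  # planted loop changes
  loops$ratio <- 1
  n_change <- cfg$n_loop_gain + cfg$n_loop_loss
  if (n_change > 0) {
    pick <- sample.int(nrow(loops), n_change)
    loops$ratio[pick[seq_len(cfg$n_loop_gain)]] <- cfg$loop_change_ratio
    if (cfg$n_loop_loss > 0)
      loops$ratio[pick[cfg$n_loop_gain + seq_len(cfg$n_loop_loss)]] <-
        1 / cfg$loop_change_ratio
  }
  loops$start1 <- loops$bin1 * cfg$hic_bin
  loops$end1 <- loops$start1 + cfg$hic_bin
  loops$start2 <- loops$bin2 * cfg$hic_bin
  loops$end2 <- loops$start2 + cfg$hic_bin
  loops$resolution <- cfg$hic_bin
  loops$name <- sprintf("loop_%d", seq_len(nrow(loops)))
  data.table::setcolorder(loops, c("chrom", "start1", "end1", "start2", "end2",
                                   "resolution", "name", "bin1", "bin2", "ratio"))

  # fixed background interaction cells (never loop cells); shared across
  # conditions so per-sample counts pair up record-for-record
  nbgi <- cfg$n_bg_interactions
  nb_hic <- as.integer(cfg$chrom_length %/% cfg$hic_bin)
  bgi <- data.table::data.table(chrom = character(), bin1 = integer(),
                                bin2 = integer(), start1 = numeric(),
                                end1 = numeric(), start2 = numeric(),
                                end2 = numeric(), name = character(),
                                ratio = numeric())
  if (nbgi > 0) {
    bchrom <- sample(chroms, nbgi, replace = TRUE)
    bd <- sample(cfg$loop_min_dist_bins:cfg$loop_max_dist_bins, nbgi,
                 replace = TRUE)
    bi <- sample.int(nb_hic - max(bd), nbgi, replace = TRUE) - 1L
    clash <- paste(bchrom, bi, bi + bd) %in%
      paste(loops$chrom, loops$bin1, loops$bin2)
    bgi <- data.table::data.table(chrom = bchrom[!clash], bin1 = bi[!clash],
                                  bin2 = (bi + bd)[!clash])
    bgi$start1 <- bgi$bin1 * cfg$hic_bin; bgi$end1 <- bgi$start1 + cfg$hic_bin
    bgi$start2 <- bgi$bin2 * cfg$hic_bin; bgi$end2 <- bgi$start2 + cfg$hic_bin
    bgi$name <- sprintf("bg_%d", seq_len(nrow(bgi)))
    bgi$ratio <- 1
  }

  ## --- CTCF / H3K9me3 sites: one per 5 kb slot ---
  n_sites <- cfg$n_peaks + cfg$n_k9_only
  slots_per_chrom <- as.integer(cfg$chrom_length %/% cfg$site_slot)
  if (n_sites > slots_per_chrom * cfg$n_chrom)
    stop("infeasible packing: more sites than 5 kb slots")
  slot_pool <- data.table::data.table(
    chrom = rep(chroms, each = slots_per_chrom),
    slot = rep(seq_len(slots_per_chrom) - 1L, cfg$n_chrom))
  pick <- sort(sample.int(nrow(slot_pool), n_sites))
  sites <- slot_pool[pick]
  # centred in the slot, aligned to the 100 bp grid
  off <- ((cfg$site_slot - cfg$peak_width) %/% 2L %/% cfg$chip_bin) * cfg$chip_bin
  sites$start <- sites$slot * cfg$site_slot + off
  sites$end <- sites$start + cfg$peak_width
  cat_pool <- c(rep("gained", cfg$n_gain),
                rep("cooccur_ctcf", cfg$n_cooccur_ctcf),
                rep("cooccur_k9", cfg$n_cooccur_k9),
                rep("plain", cfg$n_peaks - cfg$n_gain - cfg$n_cooccur_ctcf -
                      cfg$n_cooccur_k9),
                rep("k9_only", cfg$n_k9_only))
  sites$category <- sample(cat_pool)
  sites$slot <- NULL
  ctcf_peaks <- sites[sites$category != "k9_only"]
  ctcf_peaks$name <- sprintf("ctcf_%d", seq_len(nrow(ctcf_peaks)))
  k9_sites <- sites[sites$category %in%
                      c("gained", "cooccur_ctcf", "cooccur_k9", "k9_only")]
  k9_off <- ((cfg$site_slot - cfg$k9_width) %/% 2L %/% cfg$chip_bin) * cfg$chip_bin
  k9_slot <- k9_sites$start %/% cfg$site_slot
  k9_sites$start <- k9_slot * cfg$site_slot + k9_off
  k9_sites$end <- k9_sites$start + cfg$k9_width
  k9_sites$name <- sprintf("k9_%d", seq_len(nrow(k9_sites)))

  ## --- genes (non-overlapping) and repeats ---
  ba_blocks <- switch_blocks[switch_blocks$direction == "B->A"]
  gene_slot <- 2L * cfg$gene_width
  gslots_per_chrom <- as.integer(cfg$chrom_length %/% gene_slot)
  gpool <- data.table::data.table(
    chrom = rep(chroms, each = gslots_per_chrom),
    slot = rep(seq_len(gslots_per_chrom) - 1L, cfg$n_chrom))
  if (cfg$n_genes > nrow(gpool)) stop("infeasible packing: too many genes")
  gidx <- sort(sample.int(nrow(gpool), cfg$n_genes))
  genes <- gpool[gidx]
  genes$start <- genes$slot * gene_slot
  genes$end <- genes$start + cfg$gene_width
  genes$slot <- NULL
  genes$name <- sprintf("gene_%d", seq_len(nrow(genes)))
  genes$base_rate <- stats::rlnorm(cfg$n_genes, log(cfg$gene_base_rate),
                                   cfg$gene_rate_sdlog)
  genes$fc <- 1; genes$dysreg <- "stable"
  if (cfg$n_genes_up > 0) {
    up <- sample.int(cfg$n_genes, cfg$n_genes_up)
    genes$fc[up] <- cfg$gene_fc; genes$dysreg[up] <- "up"
    # couple a fraction of upregulated genes to B->A switch blocks by
    # relocating them onto free gene-width positions inside those blocks
    if (nrow(ba_blocks) > 0 && cfg$switch_gene_coupling > 0) {
      n_couple <- round(cfg$switch_gene_coupling * cfg$n_genes_up)
      cand <- data.table::rbindlist(lapply(seq_len(nrow(ba_blocks)), function(r) {
        blk <- ba_blocks[r]
        pos <- seq(blk$start_bin * cfg$hic_bin,
                   blk$end_bin * cfg$hic_bin - cfg$gene_width,
                   by = cfg$gene_width)
        data.table::data.table(chrom = blk$chrom, start = pos)
      }))
      # drop candidate positions colliding with genes that stay in place
      keep_genes <- genes[setdiff(seq_len(cfg$n_genes), up[seq_len(n_couple)])]
      collide <- vapply(seq_len(nrow(cand)), function(i) {
        any(keep_genes$chrom == cand$chrom[i] &
              keep_genes$start < cand$start[i] + cfg$gene_width &
              keep_genes$end > cand$start[i])
      }, logical(1))
      cand <- cand[!collide]
      n_couple <- min(n_couple, nrow(cand))
      if (n_couple > 0) {
        couple <- up[seq_len(n_couple)]
        pick <- cand[sample.int(nrow(cand), n_couple)]
        genes$chrom[couple] <- pick$chrom
        genes$start[couple] <- pick$start
        genes$end[couple] <- pick$start + cfg$gene_width
      }
    }
  }
  if (cfg$n_genes_down > 0) {
    down <- sample(setdiff(seq_len(cfg$n_genes),
                           which(genes$dysreg != "stable")), cfg$n_genes_down)
    genes$fc[down] <- 1 / cfg$gene_fc; genes$dysreg[down] <- "down"
  }
  data.table::setorder(genes, chrom, start)

  # repeats: exact class counts, random placement
  props <- cfg$repeat_classes
  counts <- floor(props * cfg$n_repeats)
  rem <- cfg$n_repeats - sum(counts)
  if (rem > 0) {
    frac <- props * cfg$n_repeats - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  rep_class <- sample(rep(names(counts), counts))
  rep_chrom <- sample(chroms, cfg$n_repeats, replace = TRUE)
  rep_start <- (sample.int(as.integer((cfg$chrom_length - cfg$repeat_width) %/%
                                        cfg$chip_bin), cfg$n_repeats,
                           replace = TRUE) - 1L) * cfg$chip_bin
  repeats <- data.table::data.table(chrom = rep_chrom, start = rep_start,
                                    end = rep_start + cfg$repeat_width,
                                    name = sprintf("rep_%d", seq_len(cfg$n_repeats)),
                                    class = rep_class)
  repeats$base_rate <- stats::rlnorm(cfg$n_repeats, log(cfg$repeat_base_rate),
                                     cfg$repeat_rate_sdlog)
  repeats$fc <- 1; repeats$dysreg <- "stable"
  if (cfg$n_repeats_up > 0) {
    up <- sample.int(cfg$n_repeats, cfg$n_repeats_up)
    repeats$fc[up] <- cfg$repeat_fc; repeats$dysreg[up] <- "up"
  }
  if (cfg$n_repeats_down > 0) {
    down <- sample(setdiff(seq_len(cfg$n_repeats),
                           which(repeats$dysreg != "stable")),
                   cfg$n_repeats_down)
    repeats$fc[down] <- 1 / cfg$repeat_fc; repeats$dysreg[down] <- "down"
  }
  # couple repeats to CTCF sites: gained peaks preferentially sit on SINE B2
  # copies (the retrotransposon-borne binding-site scenario); a background
  # fraction of the remaining peaks overlaps a repeat of any class
  relocate <- function(rep_rows, peak_rows) {
    off <- ((cfg$peak_width - cfg$repeat_width) %/% 2L %/% cfg$chip_bin) *
      cfg$chip_bin
    repeats$chrom[rep_rows] <<- ctcf_peaks$chrom[peak_rows]
    repeats$start[rep_rows] <<- ctcf_peaks$start[peak_rows] + off
    repeats$end[rep_rows] <<- repeats$start[rep_rows] + cfg$repeat_width
  }
  gained_rows <- which(ctcf_peaks$category == "gained")
  n_b2 <- min(round(cfg$gained_b2_fraction * length(gained_rows)),
              sum(repeats$class == "SINE_B2"))
  if (n_b2 > 0) {
    b2_rows <- which(repeats$class == "SINE_B2")[seq_len(n_b2)]
    tgt <- gained_rows[sample.int(length(gained_rows), n_b2)]
    relocate(b2_rows, tgt)
  }
  other_rows <- which(ctcf_peaks$category != "gained")
  n_bgov <- round(cfg$peak_repeat_overlap * length(other_rows))
  free_reps <- setdiff(seq_len(cfg$n_repeats),
                       which(repeats$class == "SINE_B2")[seq_len(max(n_b2, 0))])
  n_bgov <- min(n_bgov, length(free_reps))
  if (n_bgov > 0) {
    relocate(free_reps[sample.int(length(free_reps), n_bgov)],
             other_rows[sample.int(length(other_rows), n_bgov)])
  }
  data.table::setorder(repeats, chrom, start)

  structure(list(config = cfg, seed = seed, layout = layout,
                 ctcf_peaks = ctcf_peaks, k9_sites = k9_sites,
                 genes = genes, repeats = repeats,
                 compartments = comp, switch_blocks = switch_blocks,
                 tad_boundaries = tad_boundaries, loops = loops,
                 bg_interactions = bgi),
            class = "synthetic_truth")
}

#' @exportS3Method base::print
#' @noRd
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d chrom x %.0f Mb | %d CTCF peaks ",
                     "(%d gained) | %d genes, %d repeats | %d switch blocks, ",
                     "%d loops (%d changed)\n"),
              x$config$n_chrom, x$config$chrom_length / 1e6,
              nrow(x$ctcf_peaks), sum(x$ctcf_peaks$category == "gained"),
              nrow(x$genes), nrow(x$repeats), nrow(x$switch_blocks),
              nrow(x$loops), sum(x$loops$ratio != 1)))
  invisible(x)
}

# Per-condition per-bin Poisson rate for one mark over one chromosome.
site_rates <- function(truth, chrom, mark, condition) {
  cfg <- truth$config
  nb <- n_bins(truth$layout, chrom, cfg$chip_bin)
  rate <- rep(cfg$background_rate, nb)
  tbl <- if (mark == "ctcf") truth$ctcf_peaks else truth$k9_sites
  keep_rows <- tbl$chrom %in% chrom
  tbl <- tbl[keep_rows]
  if (nrow(tbl) == 0) return(rate)
  h <- vapply(seq_len(nrow(tbl)), function(i) {
    cat <- tbl$category[i]
    if (mark == "ctcf") {
      base <- switch(cat, gained = cfg$peak_height / cfg$gain_ratio,
                     cooccur_ctcf = cfg$peak_height,
                     cooccur_k9 = cfg$weak_height,
                     plain = cfg$peak_height, 0)
      if (cat == "gained" && condition == "KO") base * cfg$gain_ratio else base
    } else {
      base <- switch(cat, gained = cfg$k9_height,
                     cooccur_ctcf = cfg$weak_height,
                     cooccur_k9 = cfg$k9_height,
                     k9_only = cfg$k9_height, 0)
      if (cat == "gained" && condition == "KO")
        base / (cfg$gain_ratio ^ cfg$coupling) else base
    }
  }, numeric(1))
  for (i in seq_len(nrow(tbl))) {
    bins <- (tbl$start[i] %/% cfg$chip_bin + 1L):((tbl$end[i] - 1L) %/% cfg$chip_bin + 1L)
    rate[bins] <- rate[bins] + h[i]
  }
  rate
}

#' Simulate per-condition 1-D tracks and peak lists
#'
#' Generates raw-count ChIP (CTCF, H3K9me3), input and ATAC tracks at the
#' ChIP bin size. Peaks add signal over a flat background; in the knockout,
#' gained-CTCF sites multiply the CTCF rate by the effect ratio while their
#' H3K9me3 rate is divided by it (scaled by the coupling strength). The
#' input track is pure background. ATAC rates follow the condition's own
#' compartment labels. Truth-derived peak lists are emitted per mark.
#'
#' @param truth A `synthetic_truth` from [simulate_genome()].
#' @param condition `"WT"` or `"KO"`.
#' @param seed Integer seed.
#' @return List with `tracks` (named [signal_track()]s: ctcf, h3k9me3,
#'   input, atac) and `peaks` (named `GRanges`: ctcf, h3k9me3).
#' @export
simulate_tracks <- function(truth, condition = c("WT", "KO"), seed = 1) {
  condition <- match.arg(condition)
  cfg <- truth$config
  with_seed(sub_seed(seed, paste0("tracks_", condition)), {
    layout <- truth$layout
    vals <- list(ctcf = list(), h3k9me3 = list(), input = list(), atac = list())
    for (chrom in layout$chroms) {
      nb <- n_bins(layout, chrom, cfg$chip_bin)
      for (mark in c("ctcf", "h3k9me3")) {
        r <- site_rates(truth, chrom, mark, condition)
        vals[[mark]][[chrom]] <- rpois_od(nb, r, cfg$overdispersion)
      }
      vals$input[[chrom]] <- rpois_od(nb, rep(cfg$background_rate, nb),
                                      cfg$overdispersion)
      lab_col <- if (condition == "WT") "wt_label" else "ko_label"
      sel_rows <- which(truth$compartments$chrom == chrom)
      lab <- truth$compartments[[lab_col]][sel_rows]
      per_bin <- cfg$hic_bin %/% cfg$chip_bin
      atac_rate <- rep(ifelse(lab == "A", cfg$atac_a_rate, cfg$atac_b_rate),
                       each = per_bin)[seq_len(nb)]
      vals$atac[[chrom]] <- rpois_od(nb, atac_rate, cfg$overdispersion)
    }
    tracks <- lapply(vals, function(v)
      signal_track(v, cfg$chip_bin, layout, units = "count",
                   library_total = sum(vapply(v, sum, numeric(1)))))
    # truth-derived peak calls: a site is called where its rate is enriched
    ctcf_gr <- make_features(as.data.frame(truth$ctcf_peaks), layout)
    k9 <- truth$k9_sites
    k9_called <- if (condition == "KO" && cfg$coupling > 0)
      k9[k9$category != "gained"] else k9
    k9_gr <- make_features(as.data.frame(k9_called), layout)
    ad_log("simulate_tracks(%s): %d CTCF peaks, %d H3K9me3 peaks (seed %d)",
           condition, length(ctcf_gr), length(k9_gr), seed)
    list(tracks = tracks, peaks = list(ctcf = ctcf_gr, h3k9me3 = k9_gr))
  })
}

# Expected (noise-free) contact rate matrix for one chromosome/condition.
contact_rate_matrix <- function(truth, chrom, condition, with_loops = TRUE) {
  cfg <- truth$config
  nb <- as.integer(cfg$chrom_length %/% cfg$hic_bin)
  lab_col <- if (condition == "WT") "wt_label" else "ko_label"
  sel_rows <- which(truth$compartments$chrom == chrom)
  lab <- truth$compartments[[lab_col]][sel_rows]
  d <- abs(outer(seq_len(nb), seq_len(nb), `-`))
  rate <- cfg$hic_depth * (d + 1) ^ (-cfg$decay_alpha)
  same <- outer(lab, lab, `==`)
  rate <- rate * ifelse(same, cfg$comp_same, cfg$comp_diff)
  bounds <- truth$tad_boundaries$bin[truth$tad_boundaries$chrom == chrom]
  tid <- findInterval(0:(nb - 1), bounds)
  rate <- rate * ifelse(outer(tid, tid, `==`), cfg$tad_boost, 1)
  if (with_loops) {
    lp_rows <- truth$loops$chrom %in% chrom
    lp <- truth$loops[lp_rows]
    if (nrow(lp) > 0) {
      f <- cfg$loop_strength * (if (condition == "KO") lp$ratio else 1)
      idx <- cbind(lp$bin1 + 1L, lp$bin2 + 1L)
      rate[idx] <- rate[idx] * f
      rate[idx[, c(2, 1), drop = FALSE]] <- rate[idx]
    }
  }
  rate
}

#' Simulate a per-condition contact map with loop and interaction calls
#'
#' Each cell's expected rate is `depth * (d + 1)^-alpha` scaled by a
#' compartment factor (same-label boost, cross-label damping), a TAD factor
#' (within-domain boost) and loop spikes at planted anchor pairs; counts are
#' Poisson. The knockout applies planted compartment-switch label flips and
#' loop intensity ratios. Emitted "called" loop and multi-resolution
#' significant-interaction lists are the planted sets with per-sample q
#' values computed by an exact Poisson comparison of each cell's count to
#' its loop-free background rate (upstream loop/interaction callers are
#' inputs to the pipeline, not part of it).
#'
#' @param truth A `synthetic_truth`.
#' @param condition `"WT"` or `"KO"`.
#' @param seed Integer seed.
#' @return List with `map` (a [contact_map()]), `loops` (anchor table with
#'   `count` and `q`) and `interactions` (list per resolution with `count`
#'   and `q`).
#' @export
simulate_contacts <- function(truth, condition = c("WT", "KO"), seed = 1) {
  condition <- match.arg(condition)
  cfg <- truth$config
  with_seed(sub_seed(seed, paste0("contacts_", condition)), {
    layout <- truth$layout
    mats <- list()
    for (chrom in layout$chroms) {
      rate <- contact_rate_matrix(truth, chrom, condition)
      nb <- nrow(rate)
      ut <- which(upper.tri(rate, diag = TRUE))
      counts <- rpois_od(length(ut), rate[ut], cfg$overdispersion)
      m <- matrix(0, nb, nb)
      m[ut] <- counts
      mats[[chrom]] <- Matrix::drop0(methods::as(m, "CsparseMatrix"))
    }
    cm <- contact_map(mats, cfg$hic_bin, layout)
    # called loops: planted positions, counts from the sampled map,
    # q from the pipeline's own Poisson significance vs the loop-free rate
    loops <- data.table::copy(truth$loops)
    loops$count <- loop_counts(cm, loops)
    bg <- loop_background_rate(truth, loops, condition)
    p <- stats::ppois(loops$count - 1, bg, lower.tail = FALSE)
    loops$q <- bh_adjust(pmin(pmax(p, 1e-300), 1))
    # significant interactions at decreasing resolution
    inter <- list()
    for (ri in seq_along(cfg$interaction_res)) {
      res <- cfg$interaction_res[ri]
      frac <- cfg$interaction_res_frac[ri]
      it <- interaction_records(truth, res)
      base <- loop_background_rate(truth, it, condition) /
        (cfg$hic_bin / res) ^ 0  # background stays per-cell at the parent bin
      spike <- base * cfg$loop_strength *
        (if (condition == "KO") it$ratio else 1) * frac
      it$count <- rpois_od(nrow(it), ifelse(it$is_loop, spike, base * frac),
                           cfg$overdispersion)
      p <- stats::ppois(it$count - 1, base * frac, lower.tail = FALSE)
      it$q <- bh_adjust(pmin(pmax(p, 1e-300), 1))
      it$is_loop <- NULL; it$ratio <- NULL
      inter[[as.character(res)]] <- it
    }
    ad_log("simulate_contacts(%s): %.4g contacts (seed %d)", condition,
           cm$total, seed)
    list(map = cm, loops = loops, interactions = inter)
  })
}

#' Exact expected knockout/wild-type rate ratio at anchor pairs
#'
#' The generator's rate model makes a loop's expected contact count change
#' either through its planted intensity ratio or through a compartment
#' switch at an anchor (same-label versus cross-label contrast). This
#' returns the exact expected KO/WT rate ratio per anchor pair — the ground
#' truth for scoring differential-loop calls.
#'
#' @param truth A `synthetic_truth`.
#' @param pairs Anchor-pair table (must be at the contact-map resolution).
#' @return Numeric vector of expected rate ratios (1 = truly unchanged).
#' @export
loop_expected_ratio <- function(truth, pairs) {
  planted <- rep(1, nrow(pairs))
  key <- paste(pairs$chrom, pairs$start1, pairs$start2)
  tkey <- paste(truth$loops$chrom, truth$loops$start1, truth$loops$start2)
  hit <- match(key, tkey)
  planted[!is.na(hit)] <- truth$loops$ratio[hit[!is.na(hit)]]
  bw <- loop_background_rate(truth, pairs, "WT")
  bk <- loop_background_rate(truth, pairs, "KO")
  (bk / bw) * planted
}

# Loop-free expected rate at each anchor pair's cell (exact, from the
# generator's own rate model).
loop_background_rate <- function(truth, pairs, condition) {
  cfg <- truth$config
  vapply(seq_len(nrow(pairs)), function(i) {
    chrom <- pairs$chrom[i]
    lab_col <- if (condition == "WT") "wt_label" else "ko_label"
    comp_rows <- which(truth$compartments$chrom == chrom)
    comp <- truth$compartments[comp_rows]
    b1 <- as.integer(pairs$start1[i] %/% cfg$hic_bin)
    b2 <- as.integer(pairs$start2[i] %/% cfg$hic_bin)
    l1 <- comp[[lab_col]][b1 + 1L]; l2 <- comp[[lab_col]][b2 + 1L]
    bounds <- truth$tad_boundaries$bin[truth$tad_boundaries$chrom == chrom]
    t1 <- findInterval(b1, bounds); t2 <- findInterval(b2, bounds)
    cfg$hic_depth * (abs(b2 - b1) + 1) ^ (-cfg$decay_alpha) *
      (if (l1 == l2) cfg$comp_same else cfg$comp_diff) *
      (if (t1 == t2) cfg$tad_boost else 1)
  }, numeric(1))
}

# Planted loops and fixed background cells re-anchored at a target
# resolution: the bin containing the parent-anchor midpoint, which is always
# fully inside the parent anchor. Positions come from the truth, so the
# record set is identical across conditions.
interaction_records <- function(truth, res) {
  cfg <- truth$config
  lp <- rbind(
    truth$loops[, c("chrom", "start1", "end1", "start2", "end2", "name", "ratio")],
    truth$bg_interactions[, c("chrom", "start1", "end1", "start2", "end2",
                              "name", "ratio")])
  is_loop <- c(rep(TRUE, nrow(truth$loops)), rep(FALSE, nrow(truth$bg_interactions)))
  mid1 <- (lp$start1 + lp$end1) %/% 2
  mid2 <- (lp$start2 + lp$end2) %/% 2
  s1 <- (mid1 %/% res) * res
  s2 <- (mid2 %/% res) * res
  data.table::data.table(
    chrom = lp$chrom, start1 = s1, end1 = s1 + res,
    start2 = s2, end2 = s2 + res, resolution = res,
    name = paste0(lp$name, "_", res), is_loop = is_loop, ratio = lp$ratio)
}

#' Simulate per-condition expression count tables
#'
#' Poisson counts around each feature's base rate; planted features scale
#' their rate by the configured fold change in the knockout. Library totals
#' are the column sums.
#'
#' @param truth A `synthetic_truth`.
#' @param condition `"WT"` or `"KO"`.
#' @param seed Integer seed.
#' @return List with `genes` and `repeats` data.tables (`id`, `count`) and
#'   `totals` (named totals).
#' @export
simulate_expression <- function(truth, condition = c("WT", "KO"), seed = 1) {
  condition <- match.arg(condition)
  cfg <- truth$config
  with_seed(sub_seed(seed, paste0("expr_", condition)), {
    gr <- truth$genes$base_rate * (if (condition == "KO") truth$genes$fc else 1)
    rr <- truth$repeats$base_rate *
      (if (condition == "KO") truth$repeats$fc else 1)
    g <- data.table::data.table(id = truth$genes$name,
                                count = rpois_od(length(gr), gr, cfg$overdispersion))
    r <- data.table::data.table(id = truth$repeats$name,
                                count = rpois_od(length(rr), rr, cfg$overdispersion))
    list(genes = g, repeats = r,
         totals = c(genes = sum(g$count), repeats = sum(r$count)))
  })
}

#' Write the planted truth as TSV tables
#'
#' Lossless dump of every truth table (peaks, H3K9me3 sites, genes, repeats,
#' per-bin compartment labels, switch blocks, TAD boundaries, loops) for
#' downstream scoring; [read_truth_report()] reconstructs the tables.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
truth_report <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("ctcf_peaks", "k9_sites", "genes", "repeats", "compartments",
            "switch_blocks", "tad_boundaries", "loops", "bg_interactions")
  files <- character()
  for (tn in tabs) {
    f <- file.path(dir, paste0(tn, ".tsv"))
    data.table::fwrite(truth[[tn]], f, sep = "\t")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a truth report
#' @param dir Directory written by [truth_report()].
#' @return Named list of data.tables.
#' @export
read_truth_report <- function(dir) {
  tabs <- c("ctcf_peaks", "k9_sites", "genes", "repeats", "compartments",
            "switch_blocks", "tad_boundaries", "loops", "bg_interactions")
  out <- lapply(tabs, function(tn)
    data.table::fread(file.path(dir, paste0(tn, ".tsv")), sep = "\t"))
  names(out) <- tabs
  out
}
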