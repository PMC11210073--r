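#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator: the genome, the TAD hierarchy shape
#' (and hence the planted boundary-level distribution), and the feature
#' effects planted on top of it (TFBS density, DSB odds ratios, accessibility
#' and expression multipliers, flagged-gene placement bias). All randomness
#' downstream flows from `seed`.
#'
#' @param seed Integer seed for the single random stream.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param resolution Bin size in bp (default 10000).
#' @param n_top_tads Number of top-level TADs per genome.
#' @param nesting_depth_probs Probabilities of extra nesting depth 0..3 per
#'   top TAD (chains of strictly-inside child TADs that share no endpoint).
#' @param boundary_share_probs Probabilities that an anchor endpoint is shared
#'   by 1..4 TADs on its inner side; this drives the level histogram.
#' @param tfbs_rate_by_level Expected TFBS per bin for bin levels 0..4.
#' @param n_tf_families Number of transcription-factor families.
#' @param tfbs_pos_sd SD (bp) of TFBS positions around their bin center.
#' @param dsb_base_rate Per-bin DSB probability at level 0.
#' @param dsb_or_by_level Odds ratios (vs level 0) for levels 1..4.
#' @param dsb_mode `"bin"` plants whole-bin DSB peaks (keeps the planted odds
#'   ratio exact); `"interval"` emits variable-width peaks inside the bin for
#'   overlap-semantics tests.
#' @param dnase_level_effect Multiplicative accessibility factor, levels 0..4.
#' @param dnase_zero_prob Probability a level-0 bin has exactly zero signal.
#' @param gene_density Genes per Mb.
#' @param fpkm_level_effect Multiplicative expression factor, levels 0..4.
#' @param flagged_frac Fraction of genes flagged `repair_related`.
#' @param flagged_gene_boundary_bias Probability a flagged gene's TSS is
#'   placed inside a (random) boundary bin instead of uniformly.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_sizes = c(chr1 = 60e6, chr2 = 40e6),
    resolution = 10000,
    n_top_tads = 200,
    nesting_depth_probs = c(0.6, 0.25, 0.1, 0.05),
    boundary_share_probs = c(0.6, 0.22, 0.11, 0.07),
    tfbs_rate_by_level = c(0.2, 2, 3, 4.5, 6),
    n_tf_families = 12,
    tfbs_pos_sd = 150,
    dsb_base_rate = 0.08,
    dsb_or_by_level = c(1.5, 2, 3, 4),
    dsb_mode = c("bin", "interval"),
    dnase_level_effect = c(1, 2, 3, 4.5, 6),
    dnase_zero_prob = 0.35,
    gene_density = 8,
    fpkm_level_effect = c(1, 1.6, 2.4, 3.5, 5),
    flagged_frac = 0.08,
    flagged_gene_boundary_bias = 0.5) {
  dsb_mode <- match.arg(dsb_mode)
  stopifnot(
    resolution > 0, n_top_tads >= 1,
    length(nesting_depth_probs) == 4, length(boundary_share_probs) == 4,
    abs(sum(nesting_depth_probs) - 1) < 1e-8,
    abs(sum(boundary_share_probs) - 1) < 1e-8,
    length(tfbs_rate_by_level) == 5, all(tfbs_rate_by_level >= 0),
    dsb_base_rate > 0, dsb_base_rate < 1,
    length(dsb_or_by_level) == 4, all(dsb_or_by_level > 0),
    length(dnase_level_effect) == 5, length(fpkm_level_effect) == 5,
    flagged_gene_boundary_bias >= 0, flagged_gene_boundary_bias <= 1
  )
  structure(
    list(
      seed = as.integer(seed), chrom_sizes = chrom_sizes,
      resolution = resolution, n_top_tads = n_top_tads,
      nesting_depth_probs = nesting_depth_probs,
      boundary_share_probs = boundary_share_probs,
      tfbs_rate_by_level = tfbs_rate_by_level,
      n_tf_families = n_tf_families, tfbs_pos_sd = tfbs_pos_sd,
      dsb_base_rate = dsb_base_rate, dsb_or_by_level = dsb_or_by_level,
      dsb_mode = dsb_mode, dnase_level_effect = dnase_level_effect,
      dnase_zero_prob = dnase_zero_prob, gene_density = gene_density,
      fpkm_level_effect = fpkm_level_effect, flagged_frac = flagged_frac,
      flagged_gene_boundary_bias = flagged_gene_boundary_bias
    ),
    class = "sim_config"
  )
}

#' A seven-cell-line preset echoing typical boundary-level statistics
#'
#' Seven configurations differing only in seed (and slightly in sharing
#' probabilities), with most boundaries at levels 1-2 and few at level 4.
#'
#' @param seed Base seed; cell line k uses `seed + k`.
#' @param chrom_sizes Genome used by every cell line.
#' @return Named list of `sim_config` objects.
#' @export
seven_cell_line_preset <- function(seed = 1L,
                             chrom_sizes = c(chr1 = 30e6, chr2 = 20e6)) {
  cells <- c("GM12878", "HCT116", "IMR90", "K562", "HUVEC", "HMEC", "NHEK")
  setNames(lapply(seq_along(cells), function(k) {
    simulation_config(
      seed = seed + k,
      chrom_sizes = chrom_sizes,
      n_top_tads = 120,
      boundary_share_probs = c(0.62 - 0.01 * (k %% 3), 0.21,
                               0.11, 0.06 + 0.01 * (k %% 3))
    )
  }), cells)
}

#' Simulate a nested TAD hierarchy with planted boundary levels
#'
#' Top-level TADs are tiled along each chromosome with gaps. Each top-TAD
#' endpoint is an "anchor"; a target sharing count L ~ `boundary_share_probs`
#' is drawn and L-1 extra nested TADs are stacked on the anchor (all starting,
#' or all ending, there) with distinct interior free endpoints, so the anchor
#' is used by exactly L TADs on that side. Levels therefore arise from the
#' structure itself, never from labels. Extra nesting depth (>= 2) adds chains
#' of strictly-inside child TADs that share no endpoints, contributing only
#' level-1 boundaries. TAD sizes stay within 3-200 bins.
#'
#' @param cfg A `sim_config`.
#' @return Tibble of TADs (`chrom`, `start`, `end`, `cell_line`, `caller`)
#'   with attribute `anchor_levels` (tibble of planted anchor levels).
#' @export
simulate_tad_hierarchy <- function(cfg) {
  res <- cfg$resolution
  withr::with_seed(cfg$seed, {
    # distribute top TADs over chromosomes proportionally to length
    n_bins <- floor(cfg$chrom_sizes / res)
    n_top <- setNames(pmax(1L, round(cfg$n_top_tads * n_bins / sum(n_bins))),
                      names(n_bins))
    if (any(n_bins < n_top * 3)) {
      stop_validation("chromosomes too short for the requested top TADs")
    }
    # plain-vector accumulators: the generator runs many times in recovery
    # studies, so per-row tibble allocation is avoided
    est <- sum(n_top) * 8L
    acc_ch <- character(est); acc_s <- numeric(est); acc_e <- numeric(est)
    n_acc <- 0L
    an_ch <- character(); an_pos <- numeric(); an_side <- character()
    an_lvl <- integer()
    push <- function(ch, s, e) {
      n_acc <<- n_acc + 1L
      acc_ch[n_acc] <<- ch; acc_s[n_acc] <<- s; acc_e[n_acc] <<- e
    }
    for (ch in names(cfg$chrom_sizes)) {
      nt <- n_top[[ch]]
      avail <- n_bins[[ch]]
      # top sizes 12..40 bins (>= 12 keeps room for up to 6 stacked children),
      # gaps 1..5 bins; rescale if they do not fit
      sizes <- sample(12:40, nt, replace = TRUE)
      gaps <- sample(1:5, nt, replace = TRUE)
      need <- sum(sizes) + sum(gaps)
      if (need > avail) {
        sizes <- pmax(3L, floor(sizes * (avail - sum(gaps)) / sum(sizes)))
        need <- sum(sizes) + sum(gaps)
        if (need > avail) stop_validation("genome too small for top TADs")
      }
      starts_bin <- cumsum(c(0L, head(sizes + gaps, -1L))) + gaps
      lv_ls <- sample.int(4L, nt, replace = TRUE,
                          prob = cfg$boundary_share_probs)
      lv_rs <- sample.int(4L, nt, replace = TRUE,
                          prob = cfg$boundary_share_probs)
      depths <- sample.int(4L, nt, replace = TRUE,
                           prob = cfg$nesting_depth_probs) - 1L
      ch_an_lvl <- integer(2L * nt)
      for (i in seq_len(nt)) {
        s <- starts_bin[i]; e <- s + sizes[i]
        push(ch, s, e)
        # interior grid points keeping every stacked TAD >= 3 bins
        interior <- if (e - s >= 6L) seq(s + 3L, e - 3L) else integer()
        # left anchor (TADs stacked starting at s), right anchor (ending at e)
        n_free <- (lv_ls[i] - 1L) + (lv_rs[i] - 1L)
        free <- if (n_free > 0L && length(interior) > 0L) {
          sample(interior, min(n_free, length(interior)))
        } else integer()
        kl <- min(lv_ls[i] - 1L, length(free))
        if (kl > 0L) for (f in free[seq_len(kl)]) push(ch, s, f)
        kr <- min(lv_rs[i] - 1L, length(free) - kl)
        if (kr > 0L) for (f in free[kl + seq_len(kr)]) push(ch, f, e)
        ch_an_lvl[2L * i - 1L] <- 1L + kl
        ch_an_lvl[2L * i] <- 1L + kr
        # extra nesting depth: strictly-inside chains sharing no endpoint
        if (depths[i] >= 2L) {
          used <- sort(c(s, e, free))
          inner_s <- s; inner_e <- e
          for (dd in seq_len(depths[i] - 1L)) {
            if (inner_e - 4L < inner_s + 1L) break
            cand_s <- setdiff(seq(inner_s + 1L, inner_e - 4L), used)
            if (length(cand_s) == 0L) break
            ns <- if (length(cand_s) == 1L) cand_s else sample(cand_s, 1L)
            if (inner_e - 1L < ns + 3L) break
            cand_e <- setdiff(seq(ns + 3L, inner_e - 1L), used)
            if (length(cand_e) == 0L) break
            ne <- if (length(cand_e) == 1L) cand_e else sample(cand_e, 1L)
            push(ch, ns, ne)
            used <- sort(c(used, ns, ne))
            inner_s <- ns; inner_e <- ne
            if (inner_e - inner_s < 8L) break
          }
        }
      }
      an_ch <- c(an_ch, rep(ch, 2L * nt))
      pos_pairs <- rbind(starts_bin, starts_bin + sizes) * res
      an_pos <- c(an_pos, as.numeric(pos_pairs))
      an_side <- c(an_side, rep(c("left", "right"), nt))
      an_lvl <- c(an_lvl, ch_an_lvl)
    }
    tads <- tibble(
      chrom = acc_ch[seq_len(n_acc)], start = acc_s[seq_len(n_acc)] * res,
      end = acc_e[seq_len(n_acc)] * res,
      cell_line = "synthetic", caller = "simulated"
    )
    attr(tads, "anchor_levels") <- tibble(
      chrom = an_ch, pos = an_pos, side = an_side, target_level = an_lvl
    )
    tads
  })
}

# Structural truth: tally TAD endpoints per coordinate. Deliberately
# independent of extract_boundaries (tested for self-consistency).
boundaries_from_structure <- function(tads, resolution, cell_line = "synthetic") {
  ends <- table(paste0(tads$chrom, ":", tads$end))
  starts <- table(paste0(tads$chrom, ":", tads$start))
  keys <- sort(union(names(ends), names(starts)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  pos <- as.numeric(map_chr(parts, 2L))
  out <- tibble(
    chrom = map_chr(parts, 1L),
    bin_index = pos / resolution,
    start = pos,
    end = pos + resolution,
    left_count = as.integer(ifelse(is.na(ends[keys]), 0L, ends[keys])),
    right_count = as.integer(ifelse(is.na(starts[keys]), 0L, starts[keys])),
    cell_line = cell_line
  ) %>%
    mutate(level = pmin(4L, pmax(.data$left_count, .data$right_count))) %>%
    arrange(.data$chrom, .data$bin_index) %>%
    select("chrom", "bin_index", "start", "end", "left_count", "right_count",
           "level", "cell_line")
  attr(out, "resolution") <- resolution
  out
}

#' Expected realized boundary-level distribution of a configuration
#'
#' Each anchor drawn at level L contributes one level-L boundary and, when
#' L >= 2, L-1 extra level-1 boundaries (the free endpoints of the stacked
#' TADs); depth chains contribute further level-1 boundaries. This returns the
#' resulting expected proportions of levels 1..4 — what the realized level
#' histogram is a (approximately multinomial) sample of.
#'
#' @param cfg A `sim_config`.
#' @return Numeric vector of 4 probabilities over levels 1..4.
#' @export
planted_level_probs <- function(cfg) {
  p <- cfg$boundary_share_probs
  extra_free <- sum(p * (0:3))               # E[L - 1] free endpoints/anchor
  d <- cfg$nesting_depth_probs
  chain <- 2 * sum(d * pmax((0:3) - 1, 0))   # level-1 boundaries per top TAD
  counts <- 2 * p                            # anchors per top TAD = 2
  counts[1] <- counts[1] + 2 * extra_free + chain
  counts / sum(counts)
}

#' Simulate the full feature bundle on a TAD hierarchy
#'
#' Plants, bin by bin according to the structural boundary level:
#' TFBS counts (Poisson with level-dependent rate, positions normal around
#' the bin center, families uniform), DSB peaks (per-bin Bernoulli with
#' `logit(p) = logit(base) + log(OR_level)`), accessibility (gamma noise times
#' the level effect, with a zero-inflation for level-0 bins), and genes
#' (uniform TSS except flagged genes biased into boundary bins; log-normal
#' FPKM scaled by the level effect). All draws come from one stream seeded by
#' `cfg$seed + 1`.
#'
#' @param cfg A `sim_config`.
#' @param tads Tibble from [simulate_tad_hierarchy()].
#' @return A `synthetic_dataset` list: `tads`, `boundaries_truth`, `tfbs`,
#'   `dsb_peaks`, `dnase`, `genes`, `chrom_sizes`, `planted` (the config).
#' @export
simulate_features <- function(cfg, tads) {
  res <- cfg$resolution
  truth <- boundaries_from_structure(tads, res)
  withr::with_seed(cfg$seed + 1L, {
    bins <- bind_rows(imap(as.list(cfg$chrom_sizes), function(len, ch) {
      tibble(chrom = ch, bin = seq_len(floor(len / res)) - 1)
    })) %>%
      mutate(start = .data$bin * res, end = .data$start + res, level = 0L)
    key <- paste0(bins$chrom, ":", bins$bin)
    tk <- paste0(truth$chrom, ":", truth$bin_index)
    hit <- match(key, tk)
    bins$level <- ifelse(is.na(hit), 0L, truth$level[hit])
    lvl1 <- bins$level + 1L

    # ---- TFBS ----
    n_tfbs <- rpois(nrow(bins), cfg$tfbs_rate_by_level[lvl1])
    bi <- rep.int(seq_len(nrow(bins)), n_tfbs)
    tfbs <- tibble(
      chrom = bins$chrom[bi],
      position = pmax(1, round(
        bins$start[bi] + res / 2 + rnorm(length(bi), 0, cfg$tfbs_pos_sd)
      )),
      family_idx = sample.int(cfg$n_tf_families, length(bi), replace = TRUE)
    ) %>%
      mutate(
        tf_family = sprintf("FAM%02d", .data$family_idx),
        motif_id = sprintf("%s_M%d", .data$tf_family,
                           1L + (seq_along(.data$family_idx) %% 3L)),
        match_score = round(runif(length(bi), 8, 25), 3)
      ) %>%
      select("chrom", "position", "motif_id", "tf_family", "match_score") %>%
      arrange(.data$chrom, .data$position)

    # ---- DSB peaks ----
    base_logit <- log(cfg$dsb_base_rate / (1 - cfg$dsb_base_rate))
    or <- c(1, cfg$dsb_or_by_level)[lvl1]
    p_dsb <- stats::plogis(base_logit + log(or))
    has_dsb <- rbinom(nrow(bins), 1L, p_dsb) == 1L
    dsb_peaks <- if (cfg$dsb_mode == "bin") {
      tibble(chrom = bins$chrom[has_dsb], start = bins$start[has_dsb],
             end = bins$end[has_dsb])
    } else {
      w <- sample(500:3000, sum(has_dsb), replace = TRUE)
      ctr <- bins$start[has_dsb] + res / 2
      tibble(chrom = bins$chrom[has_dsb],
             start = pmax(0, round(ctr - w / 2)),
             end = round(ctr + w / 2))
    }

    # ---- accessibility ----
    val <- rgamma(nrow(bins), shape = 2, scale = 1) *
      cfg$dnase_level_effect[lvl1]
    zero <- bins$level == 0L &
      (runif(nrow(bins)) < cfg$dnase_zero_prob)
    val[zero] <- 0
    dnase <- tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                    value = round(val, 4)) %>%
      filter(.data$value > 0)

    # ---- genes ----
    n_genes <- max(2L, round(cfg$gene_density * sum(cfg$chrom_sizes) / 1e6))
    flagged <- runif(n_genes) < cfg$flagged_frac
    to_bdy <- flagged & (runif(n_genes) < cfg$flagged_gene_boundary_bias) &
      nrow(truth) > 0
    gbin <- sample.int(nrow(bins), n_genes, replace = TRUE)
    if (any(to_bdy)) {
      bdy_rows <- which(!is.na(hit))
      gbin[to_bdy] <- sample(bdy_rows, sum(to_bdy), replace = TRUE)
    }
    tss <- bins$start[gbin] + sample.int(res, n_genes, replace = TRUE) - 1L
    glvl <- bins$level[gbin] + 1L
    genes <- tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chrom = bins$chrom[gbin],
      tss = tss,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      length = pmin(2000000, pmax(200, round(rlnorm(n_genes, log(20000), 1)))),
      fpkm = round(rlnorm(n_genes, log(2), 1) * cfg$fpkm_level_effect[glvl], 4),
      flags = ifelse(flagged, "repair_related", NA_character_),
      age_class = sample.int(10L, n_genes, replace = TRUE),
      cs_class = sample(0:9, n_genes, replace = TRUE)
    )

    structure(
      list(tads = tads, boundaries_truth = truth, tfbs = tfbs,
           dsb_peaks = dsb_peaks, dnase = dnase, genes = genes,
           chrom_sizes = cfg$chrom_sizes, planted = cfg),
      class = "synthetic_dataset"
    )
  })
}

#' Simulate a complete dataset from a configuration
#'
#' @param cfg A `sim_config`.
#' @return A `synthetic_dataset` (see [simulate_features()]).
#' @export
simulate_dataset <- function(cfg) {
  simulate_features(cfg, simulate_tad_hierarchy(cfg))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d TADs, %d boundaries, %d TFBS, %d DSB peaks, %d genes on %d chromosome(s)\n",
    nrow(x$tads), nrow(x$boundaries_truth), nrow(x$tfbs),
    nrow(x$dsb_peaks), nrow(x$genes), length(x$chrom_sizes)
  ))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the seven files the pipeline consumes: TADs TSV, DSB BED, DNase
#' bedGraph, FIMO-style TFBS TSV, gene TSV, chrom.sizes, and the planted
#' parameters as YAML. Everything round-trips losslessly through the
#' genome-I/O readers.
#'
#' @param ds A `synthetic_dataset`.
#' @param directory Output directory (created if missing).
#' @return Named character vector: the file manifest.
#' @export
write_dataset <- function(ds, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tads = file.path(directory, "tads.tsv"),
    dsb = file.path(directory, "dsb_peaks.bed"),
    dnase = file.path(directory, "dnase.bedGraph"),
    tfbs = file.path(directory, "tfbs_fimo.tsv"),
    genes = file.path(directory, "genes.tsv"),
    chrom_sizes = file.path(directory, "chrom.sizes"),
    planted = file.path(directory, "planted.yaml")
  )
  utils::write.table(
    as.data.frame(ds$tads[c("chrom", "start", "end", "cell_line", "caller")]),
    paths["tads"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_bed(ds$dsb_peaks, paths["dsb"])
  write_bedgraph(ds$dnase, paths["dnase"])
  fimo <- data.frame(
    motif_id = ds$tfbs$motif_id,
    motif_alt_id = ds$tfbs$tf_family,
    sequence_name = ds$tfbs$chrom,
    # 2 bp match at 1-based [p, p+1]: floor((start+stop)/2) recovers p exactly
    start = ds$tfbs$position,
    stop = ds$tfbs$position + 1,
    strand = "+",
    score = ds$tfbs$match_score,
    p.value = 1e-6
  )
  names(fimo)[8] <- "p-value"
  utils::write.table(fimo, paths["tfbs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_genes(ds$genes, paths["genes"])
  utils::write.table(
    data.frame(chrom = names(ds$chrom_sizes),
               size = format(unname(ds$chrom_sizes), scientific = FALSE,
                             trim = TRUE)),
    paths["chrom_sizes"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  planted <- ds$planted
  planted$chrom_sizes <- as.list(planted$chrom_sizes)
  yaml::write_yaml(unclass(planted), paths["planted"])
  paths
}
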