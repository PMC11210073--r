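#' Run configuration for the full analysis
#'
#' Paths to the inputs plus the handful of parameters that matter, with
#' defaults mirroring the analysis conventions: 10 kb resolution, 1 kb
#' promoter pad, FPKM > 5 active genes, 300 bp kernel bandwidth, 0.1
#' contribution threshold, 1-bin padding for cross-set comparisons.
#'
#' @param tads_path TAD table (see [read_tads()]).
#' @param chrom_sizes_path Two-column chrom.sizes file.
#' @param dsb_path DSB peak BED (optional, `NULL` skips DSB analyses).
#' @param dnase_path Accessibility bedGraph (optional).
#' @param tfbs_path FIMO-style TFBS table (optional).
#' @param genes_path Gene TSV (optional).
#' @param compartments_path Labeled A/B BED (optional).
#' @param cell_line,caller Labels for the TAD set.
#' @param resolution,promoter_pad,active_fpkm_cut,bandwidth,contrib_min,pad_bins
#'   Analysis parameters (defaults 10000, 1000, 5, 300, 0.1, 1).
#' @param kde_step Density grid spacing in bp (default 10).
#' @param seed Integer seed for the level-0 random control (required).
#' @param out_dir Where `run_full_analysis()` writes its outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(tads_path, chrom_sizes_path, dsb_path = NULL,
                       dnase_path = NULL, tfbs_path = NULL, genes_path = NULL,
                       compartments_path = NULL,
                       cell_line = "cell", caller = "ontad",
                       resolution = 10000, promoter_pad = 1000,
                       active_fpkm_cut = 5, bandwidth = 300,
                       contrib_min = 0.1, pad_bins = 1, kde_step = 10,
                       seed = NULL, out_dir = tempfile("tadstrata_run_")) {
  if (is.null(seed)) {
    stop_validation("`seed` is required: the level-0 control is randomized")
  }
  stopifnot(resolution > 0, promoter_pad > 0, active_fpkm_cut > 0,
            bandwidth > 0, contrib_min > 0, pad_bins >= 0, kde_step >= 1)
  structure(
    list(tads_path = tads_path, chrom_sizes_path = chrom_sizes_path,
         dsb_path = dsb_path, dnase_path = dnase_path, tfbs_path = tfbs_path,
         genes_path = genes_path, compartments_path = compartments_path,
         cell_line = cell_line, caller = caller, resolution = resolution,
         promoter_pad = promoter_pad, active_fpkm_cut = active_fpkm_cut,
         bandwidth = bandwidth, contrib_min = contrib_min,
         pad_bins = pad_bins, kde_step = kde_step, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

read_stage <- function(stage, path, reader, ...) {
  tryCatch(reader(path, ...), error = function(e) {
    abort(sprintf("stage '%s' failed on %s: %s", stage,
                  path %||% "<missing path>", conditionMessage(e)),
          class = "tadstrata_stage_error")
  })
}

#' Run the complete boundary-stratification analysis
#'
#' Orchestrates the modules end to end: boundary extraction and level
#' histogram, level-0 random control and DSB overlap fractions with exact
#' enrichment tests, TFCR calling / complexity deciles / positional
#' annotation, gene boundary levels with flagged-gene enrichment, genome-wide
#' 10 kb bin classification with the (level x accessibility) summary, and the
#' compartment fraction per level when compartments are given. Writes
#' tab-separated tables, boundary/TFCR BEDs and a machine-readable JSON
#' summary into `cfg$out_dir`. The orchestration adds no computation: every
#' summary field is reproducible by calling the underlying function directly,
#' and identical inputs plus seed give byte-identical JSON.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with all in-memory results plus `summary` (the
#'   JSON payload) and `paths` of written files.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  chrom_sizes <- read_stage("chrom_sizes", cfg$chrom_sizes_path,
                            read_chrom_sizes)
  tads <- read_stage("tads", cfg$tads_path, read_tads,
                     cell_line = cfg$cell_line, caller = cfg$caller,
                     resolution = cfg$resolution)
  boundaries <- extract_boundaries(tads, cfg$resolution,
                                   cell_line = cfg$cell_line)
  hist <- level_histogram(boundaries)
  summary <- list(
    cell_line = cfg$cell_line,
    seed = cfg$seed,
    resolution = cfg$resolution,
    n_tads = nrow(tads),
    n_boundaries = nrow(boundaries),
    level_histogram = setNames(as.list(hist$n), paste0("level", hist$level))
  )
  results <- list(boundaries = boundaries, level_histogram = hist)

  bed <- tibble(chrom = boundaries$chrom, start = boundaries$start,
                end = boundaries$end, name = boundaries$level,
                score = pmax(boundaries$left_count, boundaries$right_count),
                strand = ".")
  paths["boundaries_bed"] <- file.path(cfg$out_dir, "boundaries.bed")
  write_bed(bed, paths["boundaries_bed"])
  paths["level_histogram"] <- write_tsv_out(hist, cfg$out_dir,
                                            "level_histogram.tsv")

  # ---- DSB analyses ----
  if (!is.null(cfg$dsb_path)) {
    dsbs <- read_stage("dsb", cfg$dsb_path, read_bed)
    control <- random_level0_control(boundaries, chrom_sizes, cfg$seed)
    frac <- overlap_fraction_by_level(bind_rows(boundaries, control), dsbs)
    paths["dsb_fractions"] <- write_tsv_out(frac, cfg$out_dir,
                                            "dsb_overlap_by_level.tsv")
    high <- filter(boundaries, .data$level >= 3)
    tests <- list()
    if (nrow(high) > 0L) {
      tests$dsb_level3plus_vs_control <- enrichment_vs_background(
        select(high, "chrom", "start", "end"),
        select(control, "chrom", "start", "end"),
        dsbs, label = "level>=3 boundaries vs level-0 control"
      )
    }
    tests$dsb_boundaries_vs_control <- enrichment_vs_background(
      select(boundaries, "chrom", "start", "end"),
      select(control, "chrom", "start", "end"),
      dsbs, label = "all boundaries vs level-0 control"
    )
    results$dsb_fractions <- frac
    results$dsb_tests <- tests
    summary$dsb_overlap_by_level <- setNames(
      as.list(round(frac$fraction, 10)), paste0("level", frac$level)
    )
    summary$dsb_enrichment <- lapply(tests, function(t) {
      list(odds_ratio = unname(t$odds_ratio), p_value = t$p_value)
    })
    paths["dsb_tests"] <- write_tsv_out(adjust_enrichments(tests),
                                        cfg$out_dir, "dsb_enrichment.tsv")
  }

  # ---- TFCRs ----
  if (!is.null(cfg$tfbs_path)) {
    tfbs <- read_stage("tfbs", cfg$tfbs_path, read_fimo)
    tfcrs <- bind_rows(lapply(unique(tfbs$chrom), function(ch) {
      prof <- density_profile(tfbs, chrom = ch, step = cfg$kde_step,
                              bandwidth = cfg$bandwidth)
      call_tfcrs(prof, tfbs, bandwidth = cfg$bandwidth,
                 contrib_min = cfg$contrib_min)
    }))
    tfcrs <- assign_tc_classes(tfcrs)
    genes <- if (!is.null(cfg$genes_path)) {
      read_stage("genes", cfg$genes_path, read_genes)
    } else NULL
    if (!is.null(genes)) {
      tfcrs <- annotate_tfcrs(tfcrs, genes, cfg$promoter_pad)
    }
    results$tfcrs <- tfcrs
    paths["tfcrs_bed"] <- file.path(cfg$out_dir, "tfcrs.bed")
    paths["tfcrs_tsv"] <- file.path(cfg$out_dir, "tfcrs.tsv")
    write_tfcrs(tfcrs, paths["tfcrs_bed"], paths["tfcrs_tsv"])
    summary$n_tfcrs <- nrow(tfcrs)
    summary$mean_tfcr_complexity <- round(mean(tfcrs$complexity), 10)
  }

  # ---- genes ----
  if (!is.null(cfg$genes_path)) {
    genes <- read_stage("genes", cfg$genes_path, read_genes)
    gene_levels <- assign_gene_boundary_levels(genes, boundaries,
                                               cfg$promoter_pad)
    paths["gene_levels"] <- write_tsv_out(gene_levels, cfg$out_dir,
                                          "gene_boundary_levels.tsv")
    results$gene_levels <- gene_levels
    flagged <- genes$gene_id[!is.na(genes$flags) &
                               grepl("repair_related", genes$flags)]
    if (length(flagged) > 0L) {
      t <- gene_set_boundary_enrichment(gene_levels, flagged,
                                        label = "repair-related genes at boundaries")
      results$flagged_gene_test <- t
      summary$flagged_gene_enrichment <- list(
        odds_ratio = unname(t$odds_ratio), p_value = t$p_value
      )
    }
  }

  # ---- genome bins ----
  if (!is.null(cfg$dsb_path) && !is.null(cfg$dnase_path) &&
      !is.null(cfg$genes_path)) {
    dnase <- read_stage("dnase", cfg$dnase_path, read_bedgraph)
    bins <- classify_genome_bins(chrom_sizes, cfg$resolution, boundaries,
                                 dnase, dsbs, genes)
    grp <- bin_group_summary(bins, genes, active_cut = cfg$active_fpkm_cut)
    results$genome_bins <- bins
    results$bin_summary <- grp
    paths["bin_summary"] <- write_tsv_out(grp, cfg$out_dir,
                                          "bin_group_summary.tsv")
    summary$mean_dsb_by_level <- setNames(
      as.list(round(tapply(bins$dsb_count, bins$level, mean), 10)),
      paste0("level", sort(unique(bins$level)))
    )
    # DSB-signal profile around boundary anchors, from the DSB peak track
    dsb_track <- validate_track(
      distinct(mutate(dsbs, value = 1), .data$chrom, .data$start,
               .data$end, .data$value)
    )
    prof <- profile_matrix(boundaries, dsb_track, chrom_sizes = chrom_sizes)
    results$dsb_profile <- prof
    paths["dsb_profile"] <- write_tsv_out(
      tibble(offset = prof$offsets, mean_signal = prof$aggregate),
      cfg$out_dir, "dsb_profile_aggregate.tsv"
    )
  }

  # ---- compartments ----
  if (!is.null(cfg$compartments_path)) {
    comps <- read_stage("compartments", cfg$compartments_path, read_bed)
    cf <- compartment_fraction_by_level(boundaries, comps)
    results$compartment_fractions <- cf
    paths["compartments"] <- write_tsv_out(cf$by_level, cfg$out_dir,
                                           "compartment_fraction_by_level.tsv")
    summary$compartment_fraction_a <- c(
      setNames(as.list(round(cf$by_level$fraction_a, 10)),
               paste0("level", cf$by_level$level)),
      list(genome_control = round(cf$genome_control, 10))
    )
  }

  paths["summary"] <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$summary <- summary
  results$paths <- paths
  invisible(results)
}

write_tsv_out <- function(df, dir, file) {
  path <- file.path(dir, file)
  df <- as.data.frame(df[!vapply(df, is.list, TRUE)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
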