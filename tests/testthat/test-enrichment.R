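iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start,
                                                 end = end)

test_that("exact test matches the enumeration oracle and fisher.test", {
  f <- fisher_exact(3, 1, 1, 3)
  expect_equal(f$p_value, 34 / 70)    # full enumeration of margins (4,4)/(4,4)
  expect_equal(f$odds_ratio, 9)

  f2 <- fisher_exact(5, 5, 5, 5)
  expect_equal(f2$p_value, 1.0)
  expect_equal(f2$odds_ratio, 1)

  withr::local_seed(21)
  for (i in 1:50) {
    t <- as.vector(stats::rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1)))
    if (min(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) == 0) next
    mine <- fisher_exact(t[1], t[2], t[3], t[4])
    expect_equal(mine$p_value, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(mine$p_value, ft$p.value, tolerance = 1e-6)
  }
})

test_that("degenerate tables follow the documented conventions", {
  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
  expect_true(is.na(fisher_exact(0, 5, 5, 0)$odds_ratio) ||
                fisher_exact(0, 5, 5, 0)$odds_ratio == 0)
  expect_error(fisher_exact(0, 0, 3, 4), "margins",
               class = "tadstrata_validation_error")
  expect_error(fisher_exact(1, 2, -1, 3), "non-negative",
               class = "tadstrata_validation_error")
  td <- tidy(fisher_exact(2, 3, 4, 5, label = "demo"))
  expect_equal(td$label, "demo")
  expect_equal(td$estimate, (2 * 5) / (3 * 4))
  g <- glance(fisher_exact(2, 3, 4, 5))
  expect_equal(g$n, 14)
})

test_that("overlap fractions hit the trivial bounds and are feature-order invariant", {
  b <- make_boundaries(c(5, 10, 20), level = c(1L, 2L, 4L))
  whole <- iv("chr1", 0, 1e7)
  f1 <- overlap_fraction_by_level(b, whole)
  expect_equal(f1$fraction, rep(1, 3))
  f0 <- overlap_fraction_by_level(b, iv(character(), double(), double()))
  expect_equal(f0$fraction, rep(0, 3))

  feats <- iv("chr1", c(51000, 95000, 201000), c(53000, 102000, 202000))
  base <- overlap_fraction_by_level(b, feats)
  shuffled <- overlap_fraction_by_level(b, feats[c(3, 1, 2), ])
  expect_equal(base, shuffled)
  split_up <- iv("chr1", c(51000, 52000, 95000, 201000),
                 c(52000, 53000, 102000, 202000))
  expect_equal(overlap_fraction_by_level(b, split_up), base)
  dup <- overlap_fraction_by_level(b, feats[c(1, 1, 2, 3, 3), ])
  expect_equal(dup, base)
})

test_that("level-0 controls avoid boundary bins and reproduce under a seed", {
  b <- make_boundaries(c(5, 10, 20, 30, 40))
  cs <- c(chr1 = 1e6)  # 100 bins
  ctrl <- random_level0_control(b, cs, seed = 7)
  expect_equal(nrow(ctrl), 5)
  expect_true(all(ctrl$level == 0L))
  expect_equal(length(unique(ctrl$bin_index)), 5)
  expect_false(any(ctrl$bin_index %in% b$bin_index))
  ctrl2 <- random_level0_control(b, cs, seed = 7)
  expect_equal(ctrl, ctrl2)
  ctrl3 <- random_level0_control(b, cs, seed = 8)
  expect_false(identical(ctrl$bin_index, ctrl3$bin_index))

  expect_error(
    random_level0_control(make_boundaries(0:4), c(chr1 = 60000), seed = 1),
    "not enough", class = "tadstrata_validation_error"
  )
})

test_that("control overlap with scattered features matches the coverage expectation", {
  withr::local_seed(22)
  cs <- c(chr1 = 2e7)  # 2000 bins
  b <- make_boundaries(sort(sample.int(2000, 100)) - 1)
  cov_frac <- 0.25
  feat_bins <- sort(sample(0:1999, 2000 * cov_frac))
  feats <- iv("chr1", feat_bins * 10000, feat_bins * 10000 + 10000)
  ctrl <- random_level0_control(b, cs, seed = 99)
  frac <- overlap_fraction_by_level(ctrl, feats)$fraction
  se <- sqrt(cov_frac * (1 - cov_frac) / 100)
  expect_lt(abs(frac - cov_frac), 3 * se + 0.02)
})

test_that("profile matrices have the right geometry and averages", {
  b <- make_boundaries(c(20, 40))
  uniform <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, value = 2.5)
  pm <- profile_matrix(b, uniform)
  expect_equal(dim(pm$matrix), c(2, 20))
  expect_true(all(abs(pm$matrix - 2.5) < 1e-12))
  expect_equal(pm$aggregate, rep(2.5, 20))

  # a 1 bp delta at the anchor center lands in the first downstream column
  center <- 20 * 10000 + 5000
  delta <- tibble::tibble(chrom = "chr1", start = center, end = center + 1,
                          value = 100)
  pm2 <- profile_matrix(make_boundaries(20), delta)
  mass_cols <- which(pm2$matrix[1, ] > 0)
  expect_equal(mass_cols, 11L)   # columns 10|11 straddle the center
  expect_equal(pm2$matrix[1, 11], 100 / 5000)

  # anchors too close to the chromosome edge are flagged and excluded
  edge <- make_boundaries(c(2, 40))
  pm3 <- profile_matrix(edge, uniform, chrom_sizes = c(chr1 = 1e6))
  expect_equal(pm3$clipped, c(TRUE, FALSE))
  expect_equal(pm3$aggregate, rep(2.5, 20))
})

test_that("genome bins are tiled, categorized and counted consistently", {
  cs <- c(chr1 = 1e5)
  b <- make_boundaries(3, level = 2L)
  dnase <- tibble::tibble(chrom = "chr1",
                          start = c(0, 20000, 40000, 60000, 80000) + 1000,
                          end = c(0, 20000, 40000, 60000, 80000) + 3000,
                          value = c(1, 2, 3, 4, 5))
  dsbs <- iv("chr1", c(5000, 29000, 29500), c(6000, 31000, 29800))
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                          tss = c(500, 800, 35000), strand = "+",
                          length = 1000, fpkm = c(10, 1, 6))
  bins <- classify_genome_bins(cs, 10000, b, dnase, dsbs, genes)
  expect_equal(nrow(bins), 10)
  expect_equal(bins$level, c(0, 0, 0, 2, rep(0, 6)))
  # mass categories: bins without signal are category 0
  expect_equal(bins$dnase_cat[bins$dnase_mass == 0], rep(0L, 5))
  expect_equal(sort(bins$dnase_cat[bins$dnase_mass > 0]),
               c(1L, 1L, 2L, 2L, 3L))
  # dsb peak spanning the bin edge counts in both bins
  expect_equal(bins$dsb_count, c(1, 0, 2, 1, rep(0, 6)))
  expect_gte(sum(bins$dsb_count), nrow(dsbs))
  expect_equal(bins$n_genes, c(2, 0, 0, 1, rep(0, 6)))
  expect_equal(bins$mean_fpkm[1], 5.5)

  grp <- bin_group_summary(bins, genes)
  expect_equal(sum(grp$n_bins), 10)
  expect_equal(grp$n_active_genes[grp$level == 0 & grp$dnase_cat ==
                                    bins$dnase_cat[1]][1], 1L)
})

test_that("per-bin means recover a planted (level x accessibility) DSB effect", {
  withr::local_seed(23)
  n <- 6000
  level <- sample(0:4, n, replace = TRUE)
  cat3 <- sample(0:3, n, replace = TRUE)
  lambda <- (1 + level) * (1 + cat3) / 4
  bins <- tibble::tibble(
    chrom = "chr1", start = (seq_len(n) - 1) * 1e4, end = seq_len(n) * 1e4,
    level = level, dnase_mass = cat3, dnase_cat = cat3,
    dsb_count = rpois(n, lambda), n_genes = 0L, mean_fpkm = NA_real_,
    gene_ids = vector("list", n)
  )
  grp <- bin_group_summary(bins, tibble::tibble(gene_id = character(),
                                                fpkm = double()))
  grp$planted <- (1 + grp$level) * (1 + grp$dnase_cat) / 4
  se <- sqrt(grp$planted / grp$n_bins)
  expect_true(all(abs(grp$mean_dsb - grp$planted) < 3.5 * se))
})

test_that("gene boundary levels take the maximum overlapped level", {
  b <- make_boundaries(c(10, 11, 50), level = c(2L, 4L, 3L))
  genes <- tibble::tibble(
    gene_id = c("in3", "spans24", "far"),
    chrom = "chr1",
    tss = c(505000, 110000, 5e6),
    strand = "+", length = 1000, fpkm = 1
  )
  gl <- assign_gene_boundary_levels(genes, b, promoter_pad = 1000)
  expect_equal(gl$level[gl$gene_id == "in3"], 3L)
  expect_equal(gl$level[gl$gene_id == "spans24"], 4L)
  expect_equal(gl$level[gl$gene_id == "far"], 0L)
})

test_that("flagged gene sets with planted boundary bias show enrichment", {
  withr::local_seed(24)
  n <- 400
  flagged <- seq_len(n) <= 120
  at_bdy <- ifelse(flagged, runif(n) < 0.6, runif(n) < 0.25)
  gl <- tibble::tibble(gene_id = paste0("g", seq_len(n)),
                       level = ifelse(at_bdy, sample(1:4, n, TRUE), 0L))
  res <- gene_set_boundary_enrichment(gl, paste0("g", which(flagged)))
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.01)
  expect_error(gene_set_boundary_enrichment(gl, character()), "empty",
               class = "tadstrata_validation_error")
})

test_that("compartment fractions per level handle A/B labels and gaps", {
  b <- make_boundaries(c(10, 20, 30), level = c(1L, 2L, 2L))
  all_a <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, name = "A")
  cf <- compartment_fraction_by_level(b, all_a)
  expect_equal(cf$by_level$fraction_a, c(1, 1))
  expect_equal(cf$genome_control, 1)

  half <- tibble::tibble(chrom = "chr1", start = c(0, 250000),
                         end = c(250000, 500000), name = c("A", "B"))
  cf2 <- compartment_fraction_by_level(b, half)
  expect_equal(cf2$genome_control, 0.5)
  expect_equal(cf2$by_level$fraction_a[cf2$by_level$level == 1], 1)  # bin 10
  expect_equal(cf2$by_level$fraction_a[cf2$by_level$level == 2], 0.5)

  gap <- tibble::tibble(chrom = "chr1", start = 0, end = 150000, name = "A")
  expect_message(cf3 <- compartment_fraction_by_level(b, gap), "unlabeled")
  expect_equal(cf3$by_level$n_unassigned[cf3$by_level$level == 2], 2L)

  expect_error(
    compartment_fraction_by_level(b, dplyr::mutate(all_a, name = "Z")),
    "labels", class = "tadstrata_validation_error"
  )
})

test_that("planted interval enrichment is detected against the background", {
  withr::local_seed(25)
  bins <- function(idx) iv("chr1", idx * 1e4, idx * 1e4 + 1e4)
  group_idx <- 0:499
  bg_idx <- 500:999
  hit <- c(runif(500) < 0.6, runif(500) < 0.25)
  feats <- bins(c(group_idx, bg_idx)[hit])
  res <- enrichment_vs_background(bins(group_idx), bins(bg_idx), feats,
                                  label = "planted")
  expect_gt(res$odds_ratio, 2)
  expect_lt(res$p_value, 1e-10)
  expect_error(enrichment_vs_background(bins(integer()), bins(bg_idx), feats),
               "empty", class = "tadstrata_validation_error")
})
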