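make_hits <- function(position, tf_family = NULL, motif_id = NULL,
                      chrom = "chr1") {
  n <- length(position)
  tibble::tibble(
    chrom = rep_len(chrom, n),
    position = position,
    motif_id = motif_id %||% paste0("M", seq_len(n)),
    tf_family = tf_family %||% paste0("F", seq_len(n)),
    match_score = 10
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("kernel contribution has the closed-form Gaussian shape", {
  expect_identical(kernel_contribution(0), 1)
  expect_equal(kernel_contribution(300), exp(-0.5))
  # the distance at which a hit stops contributing 0.1
  r <- 300 * sqrt(2 * log(10))
  expect_equal(kernel_contribution(r), 0.1)
  expect_equal(r, 644, tolerance = 1e-2)
  d <- seq(0, 2000, by = 10)
  expect_true(all(diff(kernel_contribution(d)) < 0))
})

test_that("density profile matches per-bp brute-force summation", {
  withr::local_seed(11)
  for (i in 1:20) {
    hits <- make_hits(sort(sample.int(50000, sample(1:30, 1))))
    prof <- density_profile(hits, step = 10)
    expect_equal(prof$density,
                 oracle_density(prof$pos, hits$position),
                 tolerance = 1e-12)
  }
})

test_that("profile peaks sit where the kernel algebra says", {
  one <- make_hits(1000)
  p1 <- density_profile(one)
  expect_equal(max(p1$density), 1.0)
  expect_equal(p1$pos[which.max(p1$density)], 1000)

  pair <- make_hits(c(1000, 1300))
  p2 <- density_profile(pair)
  expect_equal(max(p2$density), 2 * exp(-0.125), tolerance = 1e-9)
  expect_equal(p2$pos[which.max(p2$density)], 1150)

  far <- make_hits(c(1000, 4000))
  p3 <- density_profile(far)
  tf <- call_tfcrs(p3, far)
  expect_equal(nrow(tf), 2)
  expect_equal(tf$strength, c(1, 1), tolerance = 1e-8)
  expect_equal(tf$n_contributors, c(1L, 1L))

  expect_equal(nrow(density_profile(make_hits(integer()))), 0)
})

test_that("grid refinement only nudges peaks by at most one step", {
  # symmetric clusters keep the true density maximum on both grids
  centers <- c(5000, 25000, 60000)
  hits <- make_hits(sort(unlist(lapply(centers, function(ct) {
    ct + c(-80, -30, 30, 80)
  }))))
  t10 <- call_tfcrs(density_profile(hits, step = 10), hits)
  t5 <- call_tfcrs(density_profile(hits, step = 5), hits)
  expect_equal(nrow(t10), nrow(t5))
  expect_true(all(abs(t10$peak_pos - t5$peak_pos) <= 10))
  expect_equal(t10$strength, t5$strength, tolerance = 1e-6)
})

test_that("TFCR windows are the max contributor distance plus half a bandwidth", {
  lone <- make_hits(10000)
  tf <- call_tfcrs(density_profile(lone), lone)
  expect_equal(nrow(tf), 1)
  expect_equal(tf$n_contributors, 1L)
  expect_equal(tf$window_start, 10000 - 150)
  expect_equal(tf$window_end, 10000 + 150)

  duo <- make_hits(c(10000, 10200))
  tf2 <- call_tfcrs(density_profile(duo), duo)
  expect_equal(nrow(tf2), 1)
  d_max <- max(abs(tf2$peak_pos - duo$position))
  expect_equal(tf2$window_start, tf2$peak_pos - d_max - 150)
  expect_equal(tf2$window_end, tf2$peak_pos + d_max + 150)
})

test_that("plateaus resolve to one TFCR at the leftmost grid point", {
  prof <- tibble::tibble(chrom = "chr1", pos = seq(0, 100, by = 10),
                         density = c(0, 1, 2, 2, 2, 1, 0, 1, 2, 1, 0))
  hits <- make_hits(c(25, 80))
  tf <- call_tfcrs(prof, hits)
  expect_equal(tf$peak_pos, c(20, 80))
})

test_that("complexity collapses contributions by family", {
  expect_equal(complexity_score(tibble::tibble(tf_family = character(),
                                               contribution = double())), 0)
  one <- tibble::tibble(tf_family = "A", contribution = 1)
  expect_equal(complexity_score(one), 1)
  same_fam <- tibble::tibble(tf_family = c("A", "A"),
                             contribution = kernel_contribution(c(0, 100)))
  expect_equal(complexity_score(same_fam), 1)
  three <- tibble::tibble(tf_family = c("A", "B", "C"), contribution = 1)
  expect_equal(complexity_score(three), 3)
})

test_that("complexity is monotone in new contributors", {
  withr::local_seed(13)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    base <- tibble::tibble(
      tf_family = sample(LETTERS[1:4], n, replace = TRUE),
      contribution = runif(n, 0.1, 1)
    )
    c0 <- complexity_score(base)
    new_fam <- rbind(base, data.frame(tf_family = "Z",
                                      contribution = runif(1, 0.1, 1)))
    expect_gt(complexity_score(new_fam), c0)
    old_fam <- rbind(base, data.frame(tf_family = base$tf_family[1],
                                      contribution = runif(1, 0.1, 1)))
    expect_gte(complexity_score(old_fam), c0)
  }
})

test_that("every hit contributes only within the 0.1-threshold radius", {
  withr::local_seed(14)
  hits <- make_hits(sort(sample.int(30000, 40)))
  tf <- call_tfcrs(density_profile(hits), hits)
  expect_lte(nrow(tf), nrow(hits))
  r <- 300 * sqrt(2 * log(10))
  for (i in seq_len(nrow(tf))) {
    contrib <- tf$contributors[[i]]
    expect_true(all(contrib$contribution >= 0.1))
    expect_true(all(contrib$distance <= r))
    expect_lte(tf$complexity[i], dplyr::n_distinct(contrib$tf_family))
  }
})

test_that("TC classes are balanced ascending deciles with positional tie-break", {
  tf20 <- tibble::tibble(
    chrom = "chr1", peak_pos = seq_len(20) * 1000,
    complexity = seq(0.1, 2, by = 0.1)
  )
  out <- assign_tc_classes(tf20)
  expect_equal(as.vector(table(out$tc_class)), rep(2L, 10))
  expect_equal(out$tc_class[which.max(out$complexity)], 9L)
  expect_equal(out$tc_class[which.min(out$complexity)], 0L)

  ties <- tibble::tibble(chrom = "chr1", peak_pos = 10:1 * 1000,
                         complexity = 1)
  out2 <- assign_tc_classes(ties)
  expect_equal(sort(out2$tc_class), 0:9)
  expect_equal(out2$tc_class, 9:0)  # leftmost peak gets the lowest class

  # order invariance
  withr::local_seed(15)
  tf31 <- tibble::tibble(chrom = "chr1", peak_pos = sample(31) * 100,
                         complexity = round(runif(31), 2))
  a <- assign_tc_classes(tf31)
  shuf <- sample.int(31)
  b <- assign_tc_classes(tf31[shuf, ])
  expect_equal(b$tc_class, a$tc_class[shuf])
  expect_lte(diff(range(table(a$tc_class))), 1)

  expect_warning(out3 <- assign_tc_classes(tf31[1:5, ]), "fewer than 10")
  expect_true(all(is.na(out3$tc_class)))
})

test_that("TFCR annotation distinguishes promoter, genic and intergenic", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    tss = c(100000, 500000), strand = c("+", "-"),
    length = c(50000, 40000), fpkm = c(10, 1)
  )
  tf <- tibble::tibble(
    chrom = "chr1",
    peak_pos = c(100000, 120000, 9000000, 499000, 470000),
    strength = 1
  )
  out <- annotate_tfcrs(tf, genes, promoter_pad = 1000)
  # at TSS; in + gene body; far away; within 1 kb of - TSS; in - gene body
  expect_equal(out$annotation,
               c("promoter", "genic", "intergenic", "promoter", "genic"))
})

test_that("planted family counts are recovered from tight clusters", {
  withr::local_seed(16)
  for (k in 1:5) {
    center <- 50000
    hits <- make_hits(center + sample(-100:100, 3 * k, replace = TRUE),
                      tf_family = rep(paste0("F", seq_len(k)), each = 3))
    tf <- call_tfcrs(density_profile(hits), hits)
    expect_equal(nrow(tf), 1)
    expect_equal(tf$complexity, k, tolerance = 0.5 / k)
  }
})
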