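# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (per-endpoint recount, per-bp summation, full
# enumeration) so they share no code with the implementation they check.

# Brute-force boundary levels: recount endpoint coincidences per coordinate.
oracle_levels <- function(tads, resolution) {
  coords <- unique(rbind(
    data.frame(chrom = tads$chrom, pos = tads$start),
    data.frame(chrom = tads$chrom, pos = tads$end)
  ))
  coords <- coords[order(coords$chrom, coords$pos), ]
  out <- lapply(seq_len(nrow(coords)), function(i) {
    ch <- coords$chrom[i]; pos <- coords$pos[i]
    l <- sum(tads$chrom == ch & tads$end == pos)
    r <- sum(tads$chrom == ch & tads$start == pos)
    data.frame(chrom = ch, pos = pos, left = l, right = r,
               level = min(4, max(l, r)))
  })
  do.call(rbind, out)
}

# Random nested TAD set on one chromosome: random grid intervals, some
# forced to share endpoints so higher levels occur.
random_tad_set <- function(n, res = 10000, n_bins = 400) {
  s <- sample.int(n_bins - 4L, n, replace = TRUE) - 1L
  len <- pmin(sample(3:60, n, replace = TRUE), n_bins - s - 1L)
  tads <- data.frame(chrom = "chr1", start = s * res, end = (s + len) * res)
  # force endpoint sharing for about half the records beyond the first
  for (i in seq_len(n)[-1]) {
    if (runif(1) < 0.5) {
      j <- sample(i - 1L, 1L)
      if (runif(1) < 0.5) {
        w <- tads$end[j] - tads$start[j]
        tads$start[i] <- tads$start[j]
        tads$end[i] <- tads$start[j] +
          max(3 * res, round(w * runif(1, 0.3, 1.5) / res) * res)
      } else {
        w <- tads$end[j] - tads$start[j]
        tads$end[i] <- tads$end[j]
        tads$start[i] <- max(0, tads$end[j] -
          max(3 * res, round(w * runif(1, 0.3, 1.5) / res) * res))
      }
    }
  }
  tads
}

# Full per-bp Gaussian summation, no cutoffs.
oracle_density <- function(points, hit_pos, bandwidth = 300) {
  vapply(points, function(g) {
    sum(exp(-(g - hit_pos)^2 / (2 * bandwidth^2)))
  }, numeric(1))
}

# Two-sided Fisher p by full enumeration with choose() arithmetic (no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; N <- m1 + m2
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  denom <- choose(N, n1)
  probs <- vapply(lo:hi, function(x) {
    choose(m1, x) * choose(m2, n1 - x) / denom
  }, numeric(1))
  p_obs <- probs[(lo:hi) == a]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Tiny boundary tibble builder for overlap/consensus tests.
make_boundaries <- function(bin_index, level = 1L, chrom = "chr1",
                            res = 10000, cell_line = "cell") {
  n <- length(bin_index)
  out <- tibble::tibble(
    chrom = rep_len(chrom, n), bin_index = bin_index,
    start = bin_index * res, end = bin_index * res + res,
    left_count = rep_len(as.integer(level), n),
    right_count = 0L,
    level = rep_len(as.integer(level), n),
    cell_line = cell_line
  )
  attr(out, "resolution") <- res
  out
}
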