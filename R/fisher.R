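#' Exact two-sided Fisher test on a 2x2 table
#'
#' Direct hypergeometric computation: conditional on the margins, the
#' two-sided p-value is the sum of the point probabilities of all tables
#' whose probability does not exceed that of the observed table (with a
#' 1e-12 relative tolerance to absorb floating-point ties, the standard
#' point-probability rule). The reported odds ratio is the sample odds ratio
#' `(a*d) / (b*c)` — `Inf` when only `b*c` is 0, and `NA` when both products
#' are 0 — not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer counts; rows are in-group/out-group,
#'   columns feature+/feature-. A 2x2 matrix may be passed as `a`.
#' @param label Optional description carried into the result.
#' @return An object of class `tad_fisher` with fields `table` (named counts),
#'   `odds_ratio`, `p_value`, `label`. Has [tidy()] and [glance()] methods.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL, label = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("contingency counts must be non-negative integers")
  }
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) {
    stop_validation("all margins of the 2x2 table must be positive")
  }
  # support of the (1,1) cell given the margins
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  x <- lo:hi
  probs <- dhyper(x, m1, m2, n1)
  p_obs <- probs[x == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  p <- min(1, p)
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NA_real_
  structure(
    list(table = counts, odds_ratio = or, p_value = p,
         label = label %||% NA_character_),
    class = "tad_fisher"
  )
}

#' @export
print.tad_fisher <- function(x, ...) {
  cat("Exact 2x2 enrichment test")
  if (!is.na(x$label)) cat(" -", x$label)
  cat("\n  counts: a =", x$table["a"], " b =", x$table["b"],
      " c =", x$table["c"], " d =", x$table["d"], "\n")
  cat(sprintf("  odds ratio = %s, two-sided p = %.4g\n",
              format(x$odds_ratio, digits = 4), x$p_value))
  invisible(x)
}

#' Tidy an exact enrichment test
#'
#' @param x A `tad_fisher` object.
#' @param ... Unused.
#' @return One-row tibble with the counts, `odds_ratio` (as `estimate`) and
#'   `p.value`.
#' @method tidy tad_fisher
#' @export
tidy.tad_fisher <- function(x, ...) {
  tibble(
    label = x$label,
    a = unname(x$table["a"]), b = unname(x$table["b"]),
    c = unname(x$table["c"]), d = unname(x$table["d"]),
    estimate = x$odds_ratio,
    p.value = x$p_value
  )
}

#' Glance at an exact enrichment test
#'
#' @param x A `tad_fisher` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `n`.
#' @method glance tad_fisher
#' @export
glance.tad_fisher <- function(x, ...) {
  tibble(estimate = x$odds_ratio, p.value = x$p_value,
         n = sum(x$table))
}
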