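#' Extract TAD boundaries and assign sharing levels
#'
#' Every distinct TAD endpoint defines a boundary bin: the resolution-wide bin
#' whose start equals the endpoint coordinate. For each boundary,
#' `left_count` is the number of TADs ending there (TADs on the boundary's
#' left) and `right_count` the number starting there (TADs on its right). The
#' boundary level is `min(4, max(left_count, right_count))`: a boundary used
#' by no more than one TAD on each side is level 1, and boundaries shared by
#' four or more TADs on a side are capped at level 4 ("4+"). Level 0 is
#' reserved for non-boundary bins and random controls and is never emitted
#' here.
#'
#' @param tads Tibble of grid-snapped TADs (`chrom`, `start`, `end`), from one
#'   cell line and caller (see [read_tads()]).
#' @param resolution Bin size in bp; all TAD coordinates must be multiples.
#' @param cell_line Optional label; defaults to the TADs' `cell_line` column.
#' @return A tibble of boundaries sorted by (chrom, bin_index) with columns
#'   `chrom`, `bin_index`, `start`, `end`, `left_count`, `right_count`,
#'   `level`, `cell_line`, and attribute `resolution`.
#' @export
extract_boundaries <- function(tads, resolution, cell_line = NULL) {
  stopifnot(resolution > 0)
  if (nrow(tads) > 0 &&
      any(tads$start %% resolution != 0 | tads$end %% resolution != 0)) {
    stop_validation(
      "TAD coordinates are not multiples of `resolution`; snap them first (mixed resolutions?)"
    )
  }
  cell_line <- cell_line %||%
    (if ("cell_line" %in% names(tads) && nrow(tads) > 0)
       tads$cell_line[1] else "cell")
  if (nrow(tads) == 0L) {
    return(empty_boundary_set(resolution, cell_line))
  }
  # base aggregation: this runs thousands of times in recovery studies
  ch2 <- c(tads$chrom, tads$chrom)
  pos2 <- c(tads$end, tads$start)
  is_end <- rep(c(TRUE, FALSE), each = nrow(tads))
  key <- paste0(ch2, "\r", pos2)
  ukey <- unique(key)
  idx <- match(key, ukey)
  left_count <- tabulate(idx[is_end], nbins = length(ukey))
  right_count <- tabulate(idx[!is_end], nbins = length(ukey))
  first <- !duplicated(key)
  chrom <- ch2[first]
  pos <- pos2[first]
  lvl <- pmin(4L, pmax(left_count, right_count))
  ord <- order(chrom, pos)
  out <- tibble(
    chrom = chrom[ord],
    bin_index = pos[ord] / resolution,
    start = pos[ord],
    end = pos[ord] + resolution,
    left_count = left_count[ord],
    right_count = right_count[ord],
    level = lvl[ord],
    cell_line = cell_line
  )
  attr(out, "resolution") <- resolution
  out
}

empty_boundary_set <- function(resolution, cell_line = "cell") {
  out <- tibble(
    chrom = character(), bin_index = double(), start = double(),
    end = double(), left_count = integer(), right_count = integer(),
    level = integer(), cell_line = character()
  )
  attr(out, "resolution") <- resolution
  out
}

#' Resolution of a boundary set
#'
#' @param boundaries Tibble from [extract_boundaries()].
#' @return Bin size in bp.
#' @export
boundary_resolution <- function(boundaries) {
  res <- attr(boundaries, "resolution")
  if (is.null(res)) {
    if (nrow(boundaries) == 0L) {
      stop_validation("boundary set carries no resolution attribute")
    }
    res <- boundaries$end[1] - boundaries$start[1]
  }
  res
}

#' Expand boundary bins symmetrically
#'
#' Pads each boundary bin by `pad_bins` bins on both sides (a 10 kb bin with
#' `pad_bins = 1` becomes a 30 kb span), clipping at 0 and, when
#' `chrom_sizes` is given, at the chromosome end.
#'
#' @param boundaries Boundary tibble.
#' @param pad_bins Non-negative integer number of bins of padding per side.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Tibble with `chrom`, `start`, `end` of the expanded spans, row for
#'   row with `boundaries`.
#' @export
expand_boundaries <- function(boundaries, pad_bins = 1, chrom_sizes = NULL) {
  stopifnot(pad_bins >= 0)
  res <- boundary_resolution(boundaries)
  start <- pmax(0, boundaries$start - pad_bins * res)
  end <- boundaries$end + pad_bins * res
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[boundaries$chrom])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  tibble(chrom = boundaries$chrom, start = start, end = end)
}

#' Count the boundaries per level
#'
#' @param boundaries Boundary tibble.
#' @param levels Levels to tabulate (default 1:4).
#' @return Tibble with `level` and `n`; counts sum to `nrow(boundaries)`.
#' @export
level_histogram <- function(boundaries, levels = 1:4) {
  tibble(level = as.integer(levels)) %>%
    left_join(count(boundaries, .data$level), by = "level") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Annotate boundaries with reference-caller consensus
#'
#' For each focal boundary, counts how many reference boundary sets contain a
#' boundary whose `pad_bins`-expanded span intersects the focal boundary's
#' expanded span (both sides expanded, symmetric), then groups boundaries by
#' the level and methods-count thresholds: `both` (level >= `level_cut` and
#' methods >= `methods_cut`), `level3plus`, `methods3plus`, or `neither`.
#'
#' @param focal Boundary tibble under study.
#' @param reference_sets List of boundary tibbles from reference callers.
#' @param pad_bins Padding in bins applied to both sides (default 1, i.e. a
#'   30 kb span at 10 kb resolution).
#' @param level_cut,methods_cut Group thresholds (default 3 and 3).
#' @return `focal` with added `methods_count` and `group` columns.
#' @export
consensus_annotate <- function(focal, reference_sets, pad_bins = 1,
                               level_cut = 3, methods_cut = 3) {
  res <- boundary_resolution(focal)
  for (ref in reference_sets) {
    if (boundary_resolution(ref) != res) {
      stop_validation("focal and reference boundary sets differ in resolution")
    }
  }
  fx <- expand_boundaries(focal, pad_bins)
  methods_count <- rep(0L, nrow(focal))
  for (ref in reference_sets) {
    rx <- expand_boundaries(ref, pad_bins)
    methods_count <- methods_count + as.integer(overlaps_any0(fx, rx))
  }
  focal %>%
    mutate(
      methods_count = methods_count,
      group = dplyr::case_when(
        .data$level >= level_cut & methods_count >= methods_cut ~ "both",
        .data$level >= level_cut ~ "level3plus",
        methods_count >= methods_cut ~ "methods3plus",
        TRUE ~ "neither"
      )
    )
}

#' Cross-cell-line conservation scores
#'
#' A boundary's conservation score is the number of cell lines (including its
#' own) whose boundary set contains a boundary within `pad_bins` bins on the
#' same chromosome. With C cell lines the score ranges 1..C.
#'
#' @param sets_by_cell_line List of boundary tibbles, one per cell line.
#' @param pad_bins Matching tolerance in bins (default 1).
#' @return One tibble with all input boundaries plus a `score` column.
#' @export
conservation_scores <- function(sets_by_cell_line, pad_bins = 1) {
  stopifnot(length(sets_by_cell_line) >= 2L)
  res <- unique(map_dbl(sets_by_cell_line, boundary_resolution))
  if (length(res) != 1L) {
    stop_validation("boundary sets differ in resolution")
  }
  score_against <- function(bdy) {
    hits <- rep(0L, nrow(bdy))
    for (other in sets_by_cell_line) {
      if (nrow(other) == 0L) next
      key <- paste0(other$chrom, ":",
                    rep(other$bin_index, each = 2 * pad_bins + 1) +
                      rep(-pad_bins:pad_bins, times = nrow(other)))
      hits <- hits + as.integer(paste0(bdy$chrom, ":", bdy$bin_index) %in% key)
    }
    hits
  }
  bind_rows(lapply(sets_by_cell_line, function(bdy) {
    mutate(bdy, score = score_against(bdy))
  }))
}
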