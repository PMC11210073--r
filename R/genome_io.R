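#' Read a BED3/BED6 file of genomic intervals
#'
#' Coordinates are kept in the BED convention used throughout the package:
#' 0-based, half-open `[start, end)`. Lines starting with `#`, `track` or
#' `browser` are skipped; input order is preserved.
#'
#' @param path Path to a tab-separated BED file with at least three columns.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(tibble(
      chrom = character(), start = double(), end = double()
    ))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop_parse(sprintf(
      "%s: line %d has %d field(s); BED needs at least 3",
      path, lines$lineno[bad[1]], nf[bad[1]]
    ))
  }
  out <- tibble(
    chrom = map_chr(fields, 1L),
    start = parse_coord(fields, 2L, path, lines$lineno),
    end = parse_coord(fields, 3L, path, lines$lineno)
  )
  if (all(nf >= 4L)) out$name <- map_chr(fields, 4L)
  if (all(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(map_chr(fields, 5L)))
  }
  if (all(nf >= 6L)) out$strand <- map_chr(fields, 6L)
  validate_intervals(out, path, lines$lineno)
  out
}

#' Write genomic intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path. Tab-separated, newline-terminated.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # BED columns are positional: stop at the first absent one
  keep <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name",
                                      "score", "strand") %in% cols,
                             nomatch = 7L) - 1L)]
  df <- as.data.frame(intervals[keep])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TAD calls and snap them to the resolution grid
#'
#' Consumes OnTAD-style (or any caller's) interval tables: the first three
#' recognized columns are chrom/start/end; extra columns are ignored. Start
#' and end are independently rounded to the nearest multiple of `resolution`
#' (ties round down), because callers emit near-grid coordinates while all
#' downstream boundary arithmetic is grid-based.
#'
#' @param path Path to a tab- or whitespace-separated table; a header line is
#'   detected and skipped when the second field is non-numeric.
#' @param cell_line,caller Labels attached to every record.
#' @param resolution Bin size in bp the TADs were called at.
#' @return A tibble with `chrom`, `start`, `end`, `cell_line`, `caller`,
#'   all coordinates multiples of `resolution`.
#' @export
read_tads <- function(path, cell_line, caller, resolution) {
  stopifnot(resolution > 0)
  lines <- read_data_lines(path)
  if (length(lines$text) > 0L) {
    f1 <- strsplit(lines$text[1], "\t|\\s+")[[1]]
    if (length(f1) >= 2L && is.na(suppressWarnings(as.numeric(f1[2])))) {
      lines$text <- lines$text[-1]
      lines$lineno <- lines$lineno[-1]
    }
  }
  if (length(lines$text) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  cell_line = character(), caller = character()))
  }
  fields <- strsplit(lines$text, "\t|\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop_parse(sprintf("%s: line %d has fewer than 3 fields",
                       path, lines$lineno[bad[1]]))
  }
  out <- tibble(
    chrom = map_chr(fields, 1L),
    start = parse_coord(fields, 2L, path, lines$lineno),
    end = parse_coord(fields, 3L, path, lines$lineno)
  )
  validate_intervals(out, path, lines$lineno)
  snap_tads(out, cell_line = cell_line, caller = caller,
            resolution = resolution)
}

#' Snap TAD intervals to a resolution grid
#'
#' @param tads Tibble with `chrom`, `start`, `end`.
#' @inheritParams read_tads
#' @return Snapped tibble tagged with `cell_line` and `caller`.
#' @export
snap_tads <- function(tads, cell_line = "cell", caller = "ontad",
                      resolution = 10000) {
  start <- snap_to_grid(tads$start, resolution)
  end <- snap_to_grid(tads$end, resolution)
  sub_bin <- which(end - start < resolution)
  if (length(sub_bin) > 0L) {
    i <- sub_bin[1]
    stop_validation(sprintf(
      "TAD %s:%d-%d is shorter than one %d bp bin after snapping (%d record(s) affected)",
      tads$chrom[i], tads$start[i], tads$end[i], resolution, length(sub_bin)
    ))
  }
  tibble(
    chrom = tads$chrom, start = start, end = end,
    cell_line = cell_line, caller = caller
  )
}

# Nearest-grid rounding; exact half-bin ties round DOWN.
snap_to_grid <- function(x, resolution) {
  lo <- floor(x / resolution) * resolution
  frac <- x - lo
  out <- ifelse(frac > resolution / 2, lo + resolution, lo)
  as.numeric(out)
}

#' Read a 4-column bedGraph into a signal track
#'
#' The returned track is sorted and overlap-free per chromosome; regions not
#' covered by any record have implicit value 0.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with `chrom`, `start`, `end`, `value`, sorted by
#'   (chrom, start).
#' @export
read_bedgraph <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  value = double()))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad) > 0L) {
    stop_parse(sprintf("%s: line %d has fewer than 4 fields",
                       path, lines$lineno[bad[1]]))
  }
  out <- tibble(
    chrom = map_chr(fields, 1L),
    start = parse_coord(fields, 2L, path, lines$lineno),
    end = parse_coord(fields, 3L, path, lines$lineno),
    value = suppressWarnings(as.numeric(map_chr(fields, 4L)))
  )
  nn <- which(is.na(out$value) | !is.finite(out$value))
  if (length(nn) > 0L) {
    stop_parse(sprintf("%s: line %d has a non-numeric or non-finite value",
                       path, lines$lineno[nn[1]]))
  }
  validate_intervals(out, path, lines$lineno)
  validate_track(out)
}

#' Validate and sort a signal track
#'
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @return The sorted track; errors on overlapping intervals.
#' @export
validate_track <- function(track) {
  track <- arrange(track, .data$chrom, .data$start)
  ov <- track %>%
    group_by(.data$chrom) %>%
    filter(.data$start < dplyr::lag(.data$end, default = -Inf)) %>%
    ungroup()
  if (nrow(ov) > 0L) {
    stop_validation(sprintf(
      "signal track has overlapping intervals (first at %s:%d)",
      ov$chrom[1], ov$start[1]
    ))
  }
  track
}

#' Write a signal track as bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track[c("chrom", "start", "end", "value")])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Query a signal track at single positions
#'
#' @param track Tibble from [read_bedgraph()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Numeric vector of values; exactly 0 at uncovered positions.
#' @export
track_value_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  if (nrow(track) == 0L) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- as_granges0(track)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  out[S4Vectors::queryHits(hits)] <- track$value[S4Vectors::subjectHits(hits)]
  out
}

#' Read FIMO motif matches into TFBS hits
#'
#' FIMO reports 1-based inclusive match coordinates; each match is reduced to
#' its midpoint position `floor((start + stop) / 2)`, stored as a 0-based
#' point. Matches with p-value above `p_max` are dropped. The
#' transcription-factor family is looked up in `family_map`; motifs without an
#' entry fall back to their own motif id.
#'
#' @param path FIMO TSV (`motif_id`, `motif_alt_id`, `sequence_name`, `start`,
#'   `stop`, `strand`, `score`, `p-value`, ...) or a BED file whose name field
#'   carries the motif id.
#' @param family_map Optional named character vector or two-column data frame
#'   (`motif_id`, `tf_family`).
#' @param p_max Maximum match p-value retained (default `1e-5`).
#' @return A tibble with `chrom`, `position` (0-based midpoint), `motif_id`,
#'   `tf_family`, `match_score`.
#' @export
read_fimo <- function(path, family_map = NULL, p_max = 1e-5) {
  first <- readLines(path, n = 1L)
  header <- grepl("motif", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (ncol(df) < 5L) {
    # BED fallback: chrom start end name [score]
    if (ncol(df) < 4L) {
      stop_parse(sprintf("%s: need FIMO columns or BED4+ with motif name", path))
    }
    hits <- tibble(
      chrom = as.character(df[[1]]),
      # BED [s, e) == 1-based [s+1, e]; same midpoint rule as the FIMO branch
      position = floor((as.numeric(df[[2]]) + 1 + as.numeric(df[[3]])) / 2),
      motif_id = as.character(df[[4]]),
      match_score = if (ncol(df) >= 5L) as.numeric(df[[5]]) else NA_real_,
      p_value = NA_real_
    )
  } else {
    # FIMO layout: motif_id [motif_alt_id] sequence_name start stop strand
    # score p-value ...; tolerate the 1-column-shifted legacy layout.
    shift <- if (is.character(df[[3]]) &&
                 !is.na(suppressWarnings(as.numeric(df[[4]][1])))) 1L else 0L
    cstart <- as.numeric(df[[3L + shift]])
    cstop <- as.numeric(df[[4L + shift]])
    if (anyNA(cstart) || anyNA(cstop)) {
      stop_parse(sprintf("%s: missing or non-numeric coordinate columns", path))
    }
    hits <- tibble(
      chrom = as.character(df[[2L + shift]]),
      # midpoint of the 1-based inclusive match, floor((start + stop) / 2)
      position = floor((cstart + cstop) / 2),
      motif_id = as.character(df[[1]]),
      match_score = if (ncol(df) >= 6L + shift)
        as.numeric(df[[6L + shift]]) else NA_real_,
      p_value = if (ncol(df) >= 7L + shift)
        as.numeric(df[[7L + shift]]) else NA_real_
    )
  }
  if (any(hits$position < 0, na.rm = TRUE)) {
    stop_validation(sprintf("%s: negative TFBS position", path))
  }
  hits <- filter(hits, is.na(.data$p_value) | .data$p_value <= p_max)
  hits$tf_family <- lookup_family(hits$motif_id, family_map)
  select(hits, "chrom", "position", "motif_id", "tf_family", "match_score")
}

lookup_family <- function(motif_id, family_map) {
  if (is.null(family_map)) return(motif_id)
  if (is.data.frame(family_map)) {
    family_map <- setNames(as.character(family_map[[2]]),
                           as.character(family_map[[1]]))
  }
  fam <- unname(family_map[motif_id])
  ifelse(is.na(fam), motif_id, fam)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a `name<TAB>length` file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  sizes <- as.numeric(df[[2]])
  if (any(is.na(sizes) | sizes <= 0)) {
    stop_validation(sprintf("%s: chromosome lengths must be positive", path))
  }
  setNames(sizes, as.character(df[[1]]))
}

#' Read a headered gene table
#'
#' Expected columns: `gene_id`, `chrom`, `tss`, `strand`, `length`, `fpkm`,
#' and optionally `flags` (comma-separated labels such as `repair_related`),
#' `age_class`, `cs_class`.
#'
#' @param path Path to the TSV.
#' @return A tibble, `flags` as a comma-separated string column.
#' @export
read_genes <- function(path) {
  df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE,
                                    na.strings = c("NA", "")))
  need <- c("gene_id", "chrom", "tss", "strand", "length", "fpkm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_parse(sprintf("%s: missing gene column(s): %s",
                       path, paste(miss, collapse = ", ")))
  }
  if (any(df$fpkm < 0, na.rm = TRUE)) {
    stop_validation(sprintf("%s: fpkm must be >= 0", path))
  }
  if (any(df$length <= 0, na.rm = TRUE)) {
    stop_validation(sprintf("%s: gene length must be > 0", path))
  }
  if (!"flags" %in% names(df)) df$flags <- NA_character_
  df
}

#' Write a gene table
#'
#' @param genes Tibble as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Harmonize chromosome-name style
#'
#' Mixed sources disagree on the `chr` prefix; this adds or strips it.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"chr"` to ensure the prefix, `"plain"` to strip it,
#'   `"asis"` to leave names untouched (the default comparison is verbatim).
#' @return Character vector.
#' @export
normalize_chroms <- function(chrom, style = c("asis", "chr", "plain")) {
  style <- match.arg(style)
  if (style == "asis") return(chrom)
  bare <- sub("^chr", "", chrom)
  if (style == "chr") paste0("chr", bare) else bare
}

# ---- internal line plumbing -------------------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) {
    stop_parse(sprintf("file not found: %s", path))
  }
  txt <- readLines(path)
  lineno <- seq_along(txt)
  keep <- !grepl("^(#|track|browser)", txt) & nzchar(trimws(txt))
  list(text = txt[keep], lineno = lineno[keep])
}

parse_coord <- function(fields, idx, path, lineno) {
  x <- suppressWarnings(as.numeric(map_chr(fields, idx)))
  bad <- which(is.na(x))
  if (length(bad) > 0L) {
    stop_parse(sprintf("%s: line %d has a non-numeric coordinate",
                       path, lineno[bad[1]]))
  }
  x
}

validate_intervals <- function(df, path = "<memory>", lineno = NULL) {
  lineno <- lineno %||% seq_len(nrow(df))
  bad <- which(df$start < 0)
  if (length(bad) > 0L) {
    stop_validation(sprintf("%s: line %d: negative start coordinate",
                            path, lineno[bad[1]]))
  }
  if ("end" %in% names(df)) {
    bad <- which(df$end <= df$start)
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "%s: line %d: end (%s) must be greater than start (%s)",
        path, lineno[bad[1]],
        format(df$end[bad[1]], scientific = FALSE),
        format(df$start[bad[1]], scientific = FALSE)
      ))
    }
  }
  bad <- which(!nzchar(df$chrom))
  if (length(bad) > 0L) {
    stop_validation(sprintf("%s: line %d: empty chromosome name",
                            path, lineno[bad[1]]))
  }
  invisible(df)
}
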