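#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention: 0-based, half-open `[start, end)`.
#' Each interval carries an integer quality score in 0--1000 (the ENCODE
#' peak-score range) and a transcription-factor/antibody label (possibly
#' empty).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, `0 <= start < end`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."`. Recycled.
#' @param score Integer score in `[0, 1000]`. Recycled.
#' @param label TF/antibody identifier, may be `""`. Recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", score = 0L,
                              label = "") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    label = rep_len(as.character(label), n),
    score = rep_len(as.integer(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "label", "score", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("interval table lacks columns: ", paste(miss, collapse = ", "))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("invalid interval: require 0 <= start < end")
  if (any(x$score < 0 | x$score > 1000))
    stop("interval scores must lie in [0, 1000]")
  if (!all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

#' Parse BED into an interval table
#'
#' Reads BED3--BED6. `track`, `browser` and `#`-comment lines are skipped.
#' Missing name/score/strand columns default to `""`, `0` and `"."`.
#' Malformed data lines (non-integer coordinates, `start >= end`, out-of-range
#' score) are rejected with their line numbers.
#'
#' @param path Path to a BED file, or a character vector of lines via `text`.
#' @param text Optional character vector of BED lines (overrides `path`).
#' @return Interval `data.frame` as from [genomic_intervals()].
#' @export
parse_bed <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  bad <- character(0)
  n <- length(idx)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  label <- character(n); score <- integer(n); strand <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (ncol[i] < 3) { bad <- c(bad, sprintf("line %d: fewer than 3 columns", idx[i])); next }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      bad <- c(bad, sprintf("line %d: non-integer coordinate", idx[i])); next
    }
    if (s < 0 || s >= e) {
      bad <- c(bad, sprintf("line %d: empty or inverted interval [%d, %d)", idx[i], s, e)); next
    }
    sc <- if (ncol[i] >= 5 && nzchar(f[5])) suppressWarnings(as.integer(f[5])) else 0L
    if (is.na(sc) || sc < 0 || sc > 1000) {
      bad <- c(bad, sprintf("line %d: score outside [0, 1000]", idx[i])); next
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    label[i] <- if (ncol[i] >= 4) f[4] else ""
    score[i] <- sc
    strand[i] <- if (ncol[i] >= 6 && f[6] %in% c("+", "-", ".")) f[6] else "."
    ok[i] <- TRUE
  }
  if (length(bad) > 0)
    stop("malformed BED input:\n  ", paste(bad, collapse = "\n  "))
  genomic_intervals(chrom[ok], start[ok], end[ok],
                    strand = strand[ok], score = score[ok], label = label[ok])
}

#' Write an interval table as 6-column BED
#'
#' One tab-separated line per interval, in input order.
#'
#' @param x Interval table.
#' @param path Output path; if `NULL` the lines are returned invisibly
#'   instead of written.
#' @return Invisibly, the character vector of BED lines.
#' @export
write_bed <- function(x, path = NULL) {
  validate_intervals(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   x$chrom, x$start, x$end, x$label, x$score, x$strand)
  if (length(lines) == 0) lines <- character(0)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Derive transcript annotations (TSS) from a BED interval table
#'
#' The TSS of a plus-strand transcript is the BED `start` coordinate; of a
#' minus-strand transcript the BED `end` coordinate.
#'
#' @param bed Interval table (BED6 with transcript ids in `label`).
#' @return `data.frame` with `tx_id`, `chrom`, `strand`, `tss`.
#' @export
annotation_from_bed <- function(bed) {
  validate_intervals(bed)
  if (!all(bed$strand %in% c("+", "-")))
    stop("transcript annotations require '+' or '-' strand")
  data.frame(
    tx_id = bed$label,
    chrom = bed$chrom,
    strand = bed$strand,
    tss = ifelse(bed$strand == "+", bed$start, bed$end),
    stringsAsFactors = FALSE
  )
}

#' Build symmetric promoter windows around TSSs
#'
#' The proximal promoter is the symmetric window
#' `[tss - half_width, tss + half_width)` irrespective of strand (strand is
#' recorded for downstream use). Windows are clipped at position 0 and, when
#' chromosome sizes are supplied, at the chromosome end; clipping is flagged.
#'
#' @param annotations `data.frame` with `tx_id`, `chrom`, `strand`, `tss`.
#' @param half_width Bases on each side of the TSS (default 500).
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return `data.frame` with `tx_id`, `chrom`, `start`, `end`, `strand`,
#'   `clipped`.
#' @export
promoter_windows <- function(annotations, half_width = 500,
                             chrom_sizes = NULL) {
  stopifnot(half_width > 0)
  start <- annotations$tss - half_width
  end <- annotations$tss + half_width
  clipped <- start < 0
  start[start < 0] <- 0L
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[annotations$chrom])
    over <- !is.na(lim) & end > lim
    clipped <- clipped | over
    end[over] <- lim[over]
  }
  if (any(start >= end)) stop("promoter window collapsed to zero length")
  data.frame(
    tx_id = annotations$tx_id,
    chrom = annotations$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = annotations$strand,
    clipped = clipped,
    stringsAsFactors = FALSE
  )
}

#' Filter peaks by quality score
#'
#' Retains peaks with `score > cutoff` (strictly greater, "over" the cutoff).
#' At `cutoff = 0` all peaks are retained, including peaks scoring exactly 0
#' (the all-data mode).
#'
#' @param peaks Interval table.
#' @param cutoff Integer in `[0, 1000]` (default 500, half the maximum).
#' @return The retained subset of `peaks`.
#' @export
filter_by_score <- function(peaks, cutoff = 500) {
  stopifnot(cutoff >= 0, cutoff <= 1000)
  if (cutoff == 0) return(peaks)
  peaks[peaks$score > cutoff, , drop = FALSE]
}

#' Overlap length of two intervals
#'
#' `max(0, min(end) - max(start))` in bases when the chromosomes match,
#' otherwise 0. Vectorized over both arguments.
#'
#' @param chrom_a,start_a,end_a First interval(s).
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Integer vector of overlap lengths.
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov[chrom_a != chrom_b] <- 0L
  ov
}

#' Map peaks onto promoter windows
#'
#' Every peak overlapping a window by at least 1 bp is reported for that
#' window (coverageBed/intersectBed semantics); a peak spanning two windows is
#' reported for both. Uses an interval index (GenomicRanges) internally.
#'
#' @param windows Promoter-window table from [promoter_windows()].
#' @param peaks Interval table of peaks.
#' @return `data.frame` with one row per window-peak overlap: `tx_id`,
#'   `chrom`, `start`, `end`, `label`, `score` (peak coordinates), plus
#'   `overlap` bases.
#' @export
map_peaks_to_windows <- function(windows, peaks) {
  validate_intervals(peaks)
  empty <- data.frame(tx_id = character(), chrom = character(),
                      start = integer(), end = integer(), label = character(),
                      score = integer(), overlap = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0 || nrow(peaks) == 0) return(empty)
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L, windows$end))
  p <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(w, p, minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  wi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  data.frame(
    tx_id = windows$tx_id[wi],
    chrom = peaks$chrom[pi],
    start = peaks$start[pi],
    end = peaks$end[pi],
    label = peaks$label[pi],
    score = peaks$score[pi],
    overlap = overlap_length(windows$chrom[wi], windows$start[wi],
                             windows$end[wi], peaks$chrom[pi],
                             peaks$start[pi], peaks$end[pi]),
    stringsAsFactors = FALSE
  )
}
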