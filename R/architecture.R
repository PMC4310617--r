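#' Per-transcript Tfbs-count metrics
#'
#' Computes the four binding-site counting variants per transcript:
#' `tfbs_total` (all mapped sites), `tfbs_unique` (distinct TF labels),
#' and both counts after excluding RNA-polymerase-II-class labels
#' (`tfbs_total_nopol2`, `tfbs_unique_nopol2`). "Unique" counts a distinct
#' label once regardless of how many sites carry it.
#'
#' @param mapping Window-peak mapping from [map_peaks_to_windows()].
#' @param tx_ids Transcript ids to report (transcripts without mapped peaks
#'   get zero counts). Defaults to the ids present in `mapping`.
#' @param pol2_labels Character set of polymerase-class labels
#'   (default `c("Pol2", "POLR2A", "Pol2-4H8", "Pol3")`).
#' @return `data.frame` with `tx_id` and the four counts.
#' @export
count_metrics <- function(mapping, tx_ids = unique(mapping$tx_id),
                          pol2_labels = c("Pol2", "POLR2A", "Pol2-4H8",
                                          "Pol3")) {
  by_tx <- split(mapping$label, factor(mapping$tx_id, levels = tx_ids))
  total <- vapply(by_tx, length, integer(1))
  uniq <- vapply(by_tx, function(l) length(unique(l)), integer(1))
  nopol <- lapply(by_tx, function(l) l[!(l %in% pol2_labels)])
  total_np <- vapply(nopol, length, integer(1))
  uniq_np <- vapply(nopol, function(l) length(unique(l)), integer(1))
  data.frame(
    tx_id = tx_ids,
    tfbs_total = unname(total),
    tfbs_unique = unname(uniq),
    tfbs_total_nopol2 = unname(total_np),
    tfbs_unique_nopol2 = unname(uniq_np),
    stringsAsFactors = FALSE
  )
}

#' Summarize a distribution of per-transcript Tfbs counts
#'
#' Tukey's five numbers (minimum, lower hinge, median, upper hinge, maximum;
#' the classic five-number-summary hinge rule), the mean, standard deviation,
#' 90th percentile, and the percentages of transcripts with exactly 1 TF,
#' exactly 2 TFs, and with 1 up to 5 TFs.
#'
#' @param counts Non-empty numeric vector of per-transcript counts.
#' @return A list with `tukey_five`, `mean`, `sd`, `quantile_90`, `pct_1tf`,
#'   `pct_2tf`, `pct_le5tf`.
#' @export
summarize_distribution <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  five <- stats::fivenum(counts)
  names(five) <- c("min", "lower_hinge", "median", "upper_hinge", "max")
  list(
    tukey_five = five,
    mean = mean(counts),
    sd = stats::sd(counts),
    quantile_90 = unname(stats::quantile(counts, 0.9)),
    pct_1tf = 100 * mean(counts == 1),
    pct_2tf = 100 * mean(counts == 2),
    pct_le5tf = 100 * mean(counts >= 1 & counts <= 5)
  )
}

#' Promoter sequence composition covariates
#'
#' GC fraction, CpG dinucleotide count, and the observed/expected CpG ratio
#' `CpGoe = cpg_count * L / (nC * nG)` where `L` is the effective (non-N)
#' length; `CpGoe` is defined as 0 when `nC * nG = 0`. `N` bases are excluded
#' from all denominators.
#'
#' @param sequence A non-empty character string over `{A, C, G, T, N}`
#'   (case-insensitive).
#' @return A list with `gc`, `cpg_count`, `cpg_oe`.
#' @export
compute_composition <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- toupper(sequence)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("sequence must be over {A, C, G, T, N}")
  n_c <- sum(bases == "C")
  n_g <- sum(bases == "G")
  eff <- sum(bases != "N")
  if (eff == 0) stop("sequence contains only N")
  cpg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
  if (cpg == 1 && gregexpr("CG", s, fixed = TRUE)[[1]][1] == -1) cpg <- 0
  list(
    gc = (n_c + n_g) / eff,
    cpg_count = cpg,
    cpg_oe = if (n_c * n_g == 0) 0 else cpg * eff / (n_c * n_g)
  )
}

#' Estimate the effective promoter boundary
#'
#' Computes the mean Tfbs count per transcript over a grid of window
#' half-widths, smooths mean count versus half-width with local polynomial
#' regression (loess), and takes the first derivative of the fit. The
#' boundary is the smallest grid point after which the absolute change of the
#' derivative stays below `tolerance * max(abs(derivative))` for all larger
#' grid points - the point where the rate of increase becomes constant,
#' i.e. where TSS-proximal enrichment has decayed to the background rate.
#'
#' @param annotations Transcript annotation table (`tx_id`, `chrom`,
#'   `strand`, `tss`).
#' @param peaks Peak interval table.
#' @param grid Strictly increasing half-widths, at least 5 points. Default
#'   `c(250, 500, 1000, 2000, 3000, 4000, 5000, 7500, 10000)`.
#' @param smoothing_span loess span (default 0.6; local enough to
#'   resolve the enrichment-to-background kink on a coarse grid).
#' @param tolerance Fraction of the maximum absolute derivative below which
#'   derivative changes count as "constant" (default 0.05).
#' @param chrom_sizes Optional chromosome sizes for window clipping.
#' @return A list with `grid`, `mean_counts`, `smoothed`, `derivative`
#'   (length `length(grid) - 1`, at grid midpoints), and `boundary`.
#' @export
estimate_boundary <- function(annotations, peaks,
                              grid = c(250, 500, 1000, 2000, 3000, 4000,
                                       5000, 7500, 10000),
                              smoothing_span = 0.6, tolerance = 0.05,
                              chrom_sizes = NULL) {
  if (length(grid) < 5) stop("grid must have at least 5 points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  mean_counts <- vapply(grid, function(hw) {
    win <- promoter_windows(annotations, hw, chrom_sizes)
    m <- map_peaks_to_windows(win, peaks)
    nrow(m) / nrow(annotations)
  }, numeric(1))
  fit <- stats::loess(mean_counts ~ grid, span = smoothing_span, degree = 2)
  smoothed <- stats::predict(fit, grid)
  deriv <- diff(smoothed) / diff(grid)
  dchange <- abs(diff(deriv))
  thr <- tolerance * max(abs(deriv))
  # dchange[j] compares derivatives on either side of grid[j + 1]; the
  # boundary sits just past the last above-threshold change. A derivative
  # constant everywhere means no enrichment: boundary = first grid point.
  k <- if (all(dchange < thr)) 1L else max(which(dchange >= thr)) + 1L
  list(
    grid = grid,
    mean_counts = mean_counts,
    smoothed = smoothed,
    derivative = deriv,
    boundary = grid[k]
  )
}

#' Pairwise overlap percentages of peaks within one promoter
#'
#' For each unordered pair of peaks, `100 * overlap / union` where the union
#' length is `len_i + len_j - overlap`. Returns an empty vector when fewer
#' than 2 peaks are supplied.
#'
#' @param peaks `data.frame` with `start`, `end` (peaks in one promoter,
#'   assumed on one chromosome).
#' @return Numeric vector of percentages in `[0, 100]`, one per pair.
#' @export
pairwise_overlap_percent <- function(peaks) {
  n <- nrow(peaks)
  if (n < 2) return(numeric(0))
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  ov <- pmax(0L, pmin(peaks$end[i], peaks$end[j]) -
               pmax(peaks$start[i], peaks$start[j]))
  un <- (peaks$end[i] - peaks$start[i]) + (peaks$end[j] - peaks$start[j]) - ov
  100 * ov / un
}

#' Test for "stacked" (mutually overlapping) peak arrangement in promoters
#'
#' The observed statistic is the mean of all pairwise overlap percentages
#' pooled across promoters with at least two mapped peaks. The null pool is
#' obtained by re-placing each peak uniformly at random within its promoter
#' window, preserving per-promoter peak counts and lengths
#' (`n_randomizations` replicates). Observed and null pools are compared with
#' a Welch two-sample t-test.
#'
#' @param windows Promoter-window table.
#' @param mapping Window-peak mapping from [map_peaks_to_windows()].
#' @param n_randomizations Number of randomized datasets (default 1).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return A list with `observed_mean_overlap_pct`, `null_mean_overlap_pct`,
#'   `t_statistic`, `p_value`, `n_pairs`.
#' @export
stacking_test <- function(windows, mapping, n_randomizations = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  by_tx <- split(mapping, mapping$tx_id)
  by_tx <- by_tx[vapply(by_tx, nrow, integer(1)) >= 2]
  if (length(by_tx) == 0)
    stop("no promoter with >= 2 mapped peaks")
  win_start <- stats::setNames(windows$start, windows$tx_id)
  win_end <- stats::setNames(windows$end, windows$tx_id)
  obs <- unlist(lapply(by_tx, pairwise_overlap_percent), use.names = FALSE)
  null_one <- function(pk, tx) {
    len <- pk$end - pk$start
    ws <- win_start[[tx]]; we <- win_end[[tx]]
    len <- pmin(len, we - ws)
    new_start <- ws + floor(stats::runif(length(len)) * (we - ws - len + 1))
    pairwise_overlap_percent(data.frame(start = new_start,
                                        end = new_start + len))
  }
  null <- unlist(lapply(seq_len(n_randomizations), function(r) {
    unlist(Map(null_one, by_tx, names(by_tx)), use.names = FALSE)
  }), use.names = FALSE)
  tt <- stats::t.test(obs, null)
  list(
    observed_mean_overlap_pct = mean(obs),
    null_mean_overlap_pct = mean(null),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_pairs = length(obs)
  )
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file of promoter sequences, one record per transcript
#'   (record names = transcript ids). Requires the Biostrings package.
#' @return Named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Composition covariates for many promoter sequences
#'
#' Vectorized [compute_composition()]: one row per sequence.
#'
#' @param sequences Named character vector of promoter sequences.
#' @return `data.frame` with `tx_id`, `gc`, `cpg_count`, `cpg_oe`.
#' @export
composition_profiles <- function(sequences) {
  prof <- lapply(sequences, compute_composition)
  data.frame(
    tx_id = if (is.null(names(sequences)))
      as.character(seq_along(sequences)) else names(sequences),
    gc = vapply(prof, `[[`, numeric(1), "gc"),
    cpg_count = vapply(prof, `[[`, numeric(1), "cpg_count"),
    cpg_oe = vapply(prof, `[[`, numeric(1), "cpg_oe"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
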