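#' Read a tab-delimited TPM expression table
#'
#' Reads the OSC-style dialect used by CAGE expression tables: `#`-prefixed
#' header/comment lines are skipped, the first remaining line names the
#' columns (transcript id column first, then one column per sample), and
#' values are TPM.
#'
#' @param path Path to the file.
#' @param sample_class Optional per-sample class vector (`tissue`,
#'   `primary_cell`, `cancer_cell_line`), recycled/validated against the
#'   sample columns.
#' @return A list with `tx_ids`, `sample_ids`, `values` (numeric matrix,
#'   rows = transcripts), and `sample_class`.
#' @export
read_expression_table <- function(path, sample_class = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  tx_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  if (any(values < 0)) stop("negative TPM values")
  rownames(values) <- tx_ids
  expression_table(values, sample_class)
}

#' Assemble an expression table object
#'
#' @param values Non-negative numeric matrix, rows = transcripts (rownames =
#'   transcript ids), columns = samples (colnames = sample ids).
#' @param sample_class Optional per-sample class vector.
#' @return A list with `tx_ids`, `sample_ids`, `values`, `sample_class`.
#' @export
expression_table <- function(values, sample_class = NULL) {
  stopifnot(is.matrix(values), all(values >= 0))
  if (is.null(sample_class)) {
    sample_class <- rep("tissue", ncol(values))
  }
  if (length(sample_class) != ncol(values))
    stop("sample_class length must equal the number of sample columns")
  if (!all(sample_class %in% c("tissue", "primary_cell", "cancer_cell_line")))
    stop("sample_class must be tissue, primary_cell or cancer_cell_line")
  list(tx_ids = rownames(values), sample_ids = colnames(values),
       values = values, sample_class = sample_class)
}

#' Write an expression table in the OSC-style dialect
#'
#' @param expr Expression table from [expression_table()].
#' @param path Output path.
#' @param comment Optional comment lines (written with a `#` prefix).
#' @export
write_expression_table <- function(expr, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment) > 0) writeLines(paste0("# ", comment), con)
  tab <- data.frame(tx_id = expr$tx_ids, expr$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Breadth of expression (BoE)
#'
#' The fraction of samples in which a transcript is 'on', i.e. has TPM
#' strictly greater than the cutoff.
#'
#' @param expr_row Numeric TPM vector over samples (or a matrix for the
#'   vectorized per-row form).
#' @param cutoff_tpm 'On' threshold in TPM (default 10).
#' @return Fraction in `[0, 1]` (vector for matrix input).
#' @export
breadth <- function(expr_row, cutoff_tpm = 10) {
  stopifnot(cutoff_tpm >= 0)
  if (is.matrix(expr_row)) {
    if (ncol(expr_row) == 0) stop("zero samples")
    return(rowMeans(expr_row > cutoff_tpm))
  }
  if (length(expr_row) == 0) stop("zero samples")
  mean(expr_row > cutoff_tpm)
}

#' Expression-level summaries, overall and breadth-conditioned
#'
#' `mean_all`/`median_all`/`max_all` are taken over all samples (zeros
#' included). `mean_on`/`median_on` are restricted to samples where the
#' transcript is 'on' (TPM > cutoff) - the breadth-conditioned levels that
#' break the circular coupling between mean level and breadth - and are `NA`
#' with `on_defined = FALSE` when no sample exceeds the cutoff.
#'
#' @inheritParams breadth
#' @return A list with `mean_all`, `median_all`, `max_all`, `mean_on`,
#'   `median_on`, `on_defined`.
#' @export
level_summaries <- function(expr_row, cutoff_tpm = 10) {
  on <- expr_row > cutoff_tpm
  list(
    mean_all = mean(expr_row),
    median_all = stats::median(expr_row),
    max_all = max(expr_row),
    mean_on = if (any(on)) mean(expr_row[on]) else NA_real_,
    median_on = if (any(on)) stats::median(expr_row[on]) else NA_real_,
    on_defined = any(on)
  )
}

#' Preferential expression measure (PEM)
#'
#' A transcript's expression in each sample divided by its mean expression
#' across all samples (zeros included). The PEM vector averages to exactly 1.
#'
#' @param expr_row Numeric TPM vector with a positive mean.
#' @return Numeric PEM vector, one ratio per sample.
#' @export
pem <- function(expr_row) {
  m <- mean(expr_row)
  if (m <= 0) stop("PEM undefined for an all-zero transcript")
  expr_row / m
}

#' Average PEM of a sample over transcripts
#'
#' The unweighted mean over transcripts of the per-transcript PEM in one
#' sample; all-zero transcripts (undefined PEM) are excluded.
#'
#' @param expr Expression table from [expression_table()].
#' @param sample Sample id or column index.
#' @return Scalar average PEM.
#' @export
pem_avg <- function(expr, sample) {
  v <- expr$values
  keep <- rowMeans(v) > 0
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) stop("no transcript with defined PEM")
  mean(v[, sample] / rowMeans(v))
}

#' Convert TPM to mRNA copies per cell
#'
#' `copies = tpm * total_mrna_per_cell / 1e6`; 10 TPM corresponds to about
#' 3 copies per cell at 300,000 mRNAs per cell.
#'
#' @param tpm TPM value(s), non-negative.
#' @param total_mrna_per_cell Total mRNA molecules per cell
#'   (default 300000).
#' @return Copies per cell.
#' @export
tpm_to_copies <- function(tpm, total_mrna_per_cell = 3e5) {
  stopifnot(all(tpm >= 0), total_mrna_per_cell >= 0)
  tpm * total_mrna_per_cell / 1e6
}

#' Classify a transcript by expression breadth
#'
#' `unexpressed` (BoE = 0), `narrow` (0 < BoE <= 0.33), `intermediate`
#' (0.33 < BoE <= 0.66), `housekeeping` (BoE > 0.66). Vectorized.
#'
#' @param boe BoE value(s) in `[0, 1]`.
#' @return Character vector of class labels.
#' @export
classify_breadth <- function(boe) {
  stopifnot(all(boe >= 0 & boe <= 1))
  out <- ifelse(boe == 0, "unexpressed",
                ifelse(boe <= 0.33, "narrow",
                       ifelse(boe <= 0.66, "intermediate", "housekeeping")))
  out
}

#' Classify a transcript into the four breadth-by-richness quadrants
#'
#' `A` broad & Tfbs-rich, `B` broad & poor, `C` narrow & rich, `D` narrow &
#' poor, with rich defined as `tfbs_no >= 10` and broad as `boe > 0.33`.
#' Vectorized.
#'
#' @param tfbs_no Tfbs count(s), non-negative.
#' @param boe BoE value(s) in `[0, 1]`.
#' @return Character vector over `{"A", "B", "C", "D"}`.
#' @export
classify_quadrant <- function(tfbs_no, boe) {
  stopifnot(all(tfbs_no >= 0), all(boe >= 0 & boe <= 1))
  broad <- boe > 0.33
  rich <- tfbs_no >= 10
  ifelse(broad & rich, "A",
         ifelse(broad & !rich, "B", ifelse(rich, "C", "D")))
}

#' Per-transcript expression summary table
#'
#' BoE at each cutoff, level summaries at the active (first) cutoff, and the
#' breadth class.
#'
#' @param expr Expression table from [expression_table()].
#' @param cutoffs TPM cutoffs; the first is the active 'on' cutoff
#'   (default `c(10, 100, 1000)`).
#' @return `data.frame` with one row per transcript: `tx_id`,
#'   `boe_<cutoff>` columns, `mean_all`, `median_all`, `max_all`, `mean_on`,
#'   `median_on`, `breadth_class`.
#' @export
expression_summary <- function(expr, cutoffs = c(10, 100, 1000)) {
  v <- expr$values
  out <- data.frame(tx_id = expr$tx_ids, stringsAsFactors = FALSE)
  for (ct in cutoffs) out[[paste0("boe_", ct)]] <- breadth(v, ct)
  active <- cutoffs[1]
  on <- v > active
  any_on <- rowSums(on) > 0
  von <- v
  von[!on] <- NA
  out$mean_all <- rowMeans(v)
  out$median_all <- apply(v, 1, stats::median)
  out$max_all <- apply(v, 1, max)
  out$mean_on <- ifelse(any_on, rowMeans(von, na.rm = TRUE), NA_real_)
  out$median_on <- ifelse(any_on,
                          apply(von, 1, stats::median, na.rm = TRUE),
                          NA_real_)
  out$breadth_class <- classify_breadth(out[[paste0("boe_", active)]])
  out
}
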