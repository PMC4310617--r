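#' Correlation with t-form test statistic
#'
#' Pearson, Spearman or Kendall correlation. For Pearson and Spearman the
#' test statistic is `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees
#' of freedom; Kendall uses the normal approximation with tie correction
#' (exact enumeration for n <= 10 without ties).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param method One of `"pearson"`, `"spearman"`, `"kendall"`.
#' @return A list of class `correlation_result` with `method`, `r`, `t`,
#'   `df`, `p`, `n`. A constant input yields `r = NA` with
#'   `constant = TRUE`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired non-missing observations")
  res <- list(method = method, n = n, constant = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    res$r <- NA_real_; res$t <- NA_real_; res$df <- NA_real_
    res$p <- NA_real_; res$constant <- TRUE
    class(res) <- "correlation_result"
    return(res)
  }
  if (method %in% c("pearson", "spearman")) {
    r <- stats::cor(x, y, method = method)
    df <- n - 2
    t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
    res$r <- r; res$t <- t; res$df <- df; res$p <- p
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = (n <= 10)))
    res$r <- unname(ct$estimate)
    res$t <- unname(ct$statistic)
    res$df <- NA_real_
    res$p <- ct$p.value
  }
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, stat = %.4f, df = %s, p = %.4g, n = %d\n",
              x$method, x$r, x$t,
              ifelse(is.na(x$df), "-", format(x$df)), x$p, x$n))
  invisible(x)
}

#' Rank-based (Spearman) partial correlation
#'
#' All columns are rank-transformed, then the partial correlation of
#' `target_col` with `other_col` given `control_cols` is computed by the
#' precision-matrix method (inverse of the correlation matrix). With an empty
#' control set this reproduces the plain Spearman correlation.
#'
#' @param table `data.frame` of numeric columns; rows with missing values in
#'   the used columns are dropped.
#' @param target_col,other_col Column names of the two primary variables.
#' @param control_cols Character vector of columns to control for
#'   simultaneously (may be empty).
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(table, target_col, other_col,
                                control_cols = character(0)) {
  cols <- c(target_col, other_col, control_cols)
  if (anyDuplicated(cols)) stop("duplicated column selection")
  sub <- table[, cols, drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  if (nrow(sub) < length(control_cols) + 3)
    stop("need at least ", length(control_cols) + 3, " complete rows")
  ranked <- vapply(sub, rank, numeric(nrow(sub)))
  if (length(control_cols) == 0)
    return(stats::cor(ranked[, 1], ranked[, 2]))
  cm <- stats::cor(ranked)
  ev <- eigen(cm, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    loading <- abs(ev$vectors[, which.min(ev$values)])
    stop("singular correlation matrix; collinear columns: ",
         paste(cols[loading > 1e-6], collapse = ", "))
  }
  pm <- solve(cm)
  -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
}

#' Promoter-shuffle permutation null for a count-breadth correlation
#'
#' Each replicate permutes the Tfbs-count vector (sampling without
#' replacement, i.e. shuffling the promoter-to-transcript assignment) and
#' records the t-statistic of the Pearson correlation with BoE. The
#' empirical p-value uses the +1 pseudocount:
#' `(1 + #(|replicate| >= |observed|)) / (1 + n_reps)`.
#'
#' @param tfbs_counts,boe Equal-length numeric vectors.
#' @param n_reps Number of permutation replicates (>= 1, default 1000).
#' @param seed Integer seed; deterministic given the seed.
#' @return A list with `observed_stat`, `replicates`, `n_reps`, `seed`,
#'   `empirical_p`.
#' @export
shuffle_null <- function(tfbs_counts, boe, n_reps = 1000, seed = NULL) {
  stopifnot(length(tfbs_counts) == length(boe), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- correlate(tfbs_counts, boe, "pearson")$t
  reps <- vapply(seq_len(n_reps), function(i) {
    correlate(sample(tfbs_counts), boe, "pearson")$t
  }, numeric(1))
  list(
    observed_stat = obs,
    replicates = reps,
    n_reps = n_reps,
    seed = seed,
    empirical_p = (1 + sum(abs(reps) >= abs(obs))) / (1 + n_reps)
  )
}

#' Agglomerative clustering under correlation distance
#'
#' Pairwise column distance `1 - r` (Pearson by default), average-linkage
#' agglomeration. Columns are ordered by name before clustering so the leaf
#' order is deterministic and tie-breaks are by column name.
#'
#' @param matrix Numeric matrix with named, non-constant columns (>= 2).
#' @param method Correlation type: `"pearson"`, `"spearman"`, `"kendall"`.
#' @return An `hclust` object.
#' @export
cluster_by_correlation <- function(matrix,
                                   method = c("pearson", "spearman",
                                              "kendall")) {
  method <- match.arg(method)
  if (ncol(matrix) < 2) stop("need at least 2 columns")
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(matrix)[sds == 0], collapse = ", "))
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(matrix, method = method))
  stats::hclust(d, method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @param path Output path; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_to_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Support-vector-machine predictor of expression breadth or PEM
#'
#' Fits a radial-kernel SVM (regression or binary classification) on a
#' seeded random half of the rows and evaluates on the held-out half,
#' together with two controls computed on the same split: a scrambled
#' control (response permuted in training; negative control) and a retained
#' control (response included as a feature; positive control). Features are
#' scaled and centered on the training half (libsvm scaling). Regression
#' accuracy is the Pearson correlation between predicted and observed
#' responses on the held-out half. In binary mode the response is the
#' narrow/not-narrow label at BoE 0.33 and accuracy is the area under the
#' ROC curve averaged over `n_cv` random-half runs.
#'
#' @param features Numeric matrix, one row per transcript (e.g. per-TF
#'   counts, optionally plus GC/CpG covariates).
#' @param response Numeric response (BoE or PEM) for regression mode; for
#'   binary mode still numeric BoE, dichotomized at 0.33 internally.
#' @param mode `"regression"` or `"binary"`.
#' @param cost,gamma,epsilon Radial-kernel hyperparameters
#'   (defaults 1, 0.01, 0.1).
#' @param split_seed Seed for the half/half split (default 1).
#' @param n_cv Number of cross-validation runs for the binary AUC
#'   (default 10).
#' @return A list of class `predictor_report` with `mode`, `r_prediction`,
#'   `r_scrambled`, `r_retained`, `auc` (binary mode, else `NA`),
#'   `split_seed`, `hyperparameters`.
#' @export
fit_predictor <- function(features, response,
                          mode = c("regression", "binary"),
                          cost = 1, gamma = 0.01, epsilon = 0.1,
                          split_seed = 1, n_cv = 10) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 50) stop("fewer than 50 rows: split too small")
  if (length(response) != n) stop("response length mismatch")
  set.seed(split_seed)
  train <- sample.int(n, floor(n / 2))
  test <- setdiff(seq_len(n), train)
  hp <- list(cost = cost, gamma = gamma, epsilon = epsilon)

  fit_eval <- function(xtr, ytr, xte, yte) {
    # sparse count features are often constant within one half; libsvm's
    # scale warning for those columns is expected and benign
    fit <- suppressWarnings(
      e1071::svm(x = xtr, y = ytr, type = "eps-regression",
                 kernel = "radial", cost = cost, gamma = gamma,
                 epsilon = epsilon, scale = TRUE))
    pred <- stats::predict(fit, xte)
    stats::cor(pred, yte)
  }

  rep <- list(mode = mode, split_seed = split_seed, hyperparameters = hp,
              auc = NA_real_)
  if (mode == "regression") {
    rep$r_prediction <- fit_eval(features[train, , drop = FALSE],
                                 response[train],
                                 features[test, , drop = FALSE],
                                 response[test])
    rep$r_scrambled <- fit_eval(features[train, , drop = FALSE],
                                sample(response[train]),
                                features[test, , drop = FALSE],
                                response[test])
    retained <- cbind(features, .response = response)
    rep$r_retained <- fit_eval(retained[train, , drop = FALSE],
                               response[train],
                               retained[test, , drop = FALSE],
                               response[test])
  } else {
    lab <- factor(ifelse(response <= 0.33, "narrow", "broad"),
                  levels = c("narrow", "broad"))
    auc_one <- function(tr, te, y) {
      fit <- suppressWarnings(
        e1071::svm(x = features[tr, , drop = FALSE], y = y[tr],
                   type = "C-classification", kernel = "radial",
                   cost = cost, gamma = gamma, scale = TRUE))
      dv <- attr(stats::predict(fit, features[te, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      as.numeric(pROC::auc(pROC::roc(response = y[te],
                                     predictor = as.numeric(dv[, 1]),
                                     quiet = TRUE, direction = "auto")))
    }
    aucs <- vapply(seq_len(n_cv), function(i) {
      tr <- sample.int(n, floor(n / 2))
      auc_one(tr, setdiff(seq_len(n), tr), lab)
    }, numeric(1))
    rep$auc <- mean(aucs)
    rep$r_prediction <- NA_real_
    rep$r_scrambled <- NA_real_
    rep$r_retained <- NA_real_
  }
  class(rep) <- "predictor_report"
  rep
}

#' @export
print.predictor_report <- function(x, ...) {
  cat(sprintf("SVM predictor (%s mode, cost=%g gamma=%g epsilon=%g)\n",
              x$mode, x$hyperparameters$cost, x$hyperparameters$gamma,
              x$hyperparameters$epsilon))
  if (x$mode == "regression") {
    cat(sprintf("  prediction r = %.4f, scrambled r = %.4f, retained r = %.4f\n",
                x$r_prediction, x$r_scrambled, x$r_retained))
  } else {
    cat(sprintf("  mean AUC over cross-validation runs = %.4f\n", x$auc))
  }
  invisible(x)
}

#' Per-transcript, per-TF count matrix
#'
#' Rows are transcripts, columns TF labels, entries the number of mapped
#' binding sites of that TF in the transcript's promoter window. These
#' per-TF count vectors are the feature rows of the SVM predictor.
#'
#' @param mapping Window-peak mapping from [map_peaks_to_windows()].
#' @param tx_ids Transcript ids to report (zero rows for unmapped ones).
#' @param labels TF labels to report (defaults to those present).
#' @return Integer matrix `length(tx_ids) x length(labels)`.
#' @export
tf_count_matrix <- function(mapping, tx_ids = unique(mapping$tx_id),
                            labels = sort(unique(mapping$label))) {
  m <- table(factor(mapping$tx_id, levels = tx_ids),
             factor(mapping$label, levels = labels))
  out <- matrix(as.integer(m), nrow = length(tx_ids),
                dimnames = list(tx_ids, labels))
  out
}
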