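test_that("correlate returns the t-form statistic for pearson and spearman", {
  set.seed(2)
  x <- rnorm(40); y <- x + rnorm(40)
  for (m in c("pearson", "spearman")) {
    res <- correlate(x, y, m)
    expect_equal(res$df, 38)
    expect_equal(res$t, res$r * sqrt(38 / (1 - res$r^2)))
    expect_equal(res$p, 2 * pt(-abs(res$t), 38))
  }
  # pearson t and p agree with the reference implementation
  ct <- cor.test(x, y)
  res <- correlate(x, y, "pearson")
  expect_equal(res$t, unname(ct$statistic))
  expect_equal(res$p, ct$p.value)
  expect_equal(correlate(x, x)$r, 1)
  kd <- correlate(x, y, "kendall")
  expect_equal(kd$r, unname(cor.test(x, y, method = "kendall",
                                     exact = FALSE)$estimate))
  cst <- correlate(rep(1, 10), rnorm(10))
  expect_true(cst$constant && is.na(cst$r))
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("independent draws decorrelate and spearman is rank-invariant", {
  set.seed(5)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(correlate(x, y)$r), 0.05)
  z <- rexp(200)
  expect_equal(correlate(z, y[1:200], "spearman")$r,
               correlate(exp(3 * z), y[1:200], "spearman")$r)
})

test_that("partial correlation with empty controls is plain spearman", {
  set.seed(6)
  tab <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  expect_equal(partial_correlation(tab, "a", "b"),
               correlate(tab$a, tab$b, "spearman")$r)
})

test_that("partial correlation removes a planted mediated dependence", {
  set.seed(16)
  n <- 3000
  x <- rnorm(n)
  m <- x + rnorm(n, 0, 0.4)
  y <- m + rnorm(n, 0, 0.4)  # y depends on x only through m
  tab <- data.frame(x = x, m = m, y = y)
  expect_gt(correlate(x, y, "spearman")$r, 0.5)
  expect_lt(abs(partial_correlation(tab, "x", "y", "m")), 0.1)
  # symmetric in the two primary arguments
  expect_equal(partial_correlation(tab, "x", "y", "m"),
               partial_correlation(tab, "y", "x", "m"))
  # collinear controls are named
  tab$m2 <- tab$m
  expect_error(partial_correlation(tab, "x", "y", c("m", "m2")),
               "singular.*m.*m2")
  expect_error(partial_correlation(tab[1:3, ], "x", "y", "m"), "complete rows")
})

test_that("promoter-shuffle null is seeded, centered and detects coupling", {
  set.seed(30)
  counts <- rpois(400, 6)
  boe <- plogis(0.4 * counts + rnorm(400) - 3)  # planted strong coupling
  nd <- shuffle_null(counts, boe, n_reps = 499, seed = 9)
  expect_equal(nd$empirical_p, 1 / 500)  # minimum possible p
  expect_identical(nd$replicates,
                   shuffle_null(counts, boe, n_reps = 499, seed = 9)$replicates)
  # replicates are centered under permutation
  expect_lt(abs(mean(nd$replicates)),
            3 * sd(nd$replicates) / sqrt(nd$n_reps))
  expect_equal(nd$empirical_p,
               (1 + sum(abs(nd$replicates) >= abs(nd$observed_stat))) /
                 (1 + nd$n_reps))
})

test_that("correlation-distance clustering recovers planted blocks", {
  set.seed(33)
  base1 <- rnorm(300); base2 <- rnorm(300)
  m <- cbind(a1 = base1 + rnorm(300, 0, 0.3),
             a2 = base1 + rnorm(300, 0, 0.3),
             a3 = base1 + rnorm(300, 0, 0.3),
             b1 = base2 + rnorm(300, 0, 0.3),
             b2 = base2 + rnorm(300, 0, 0.3))
  hc <- cluster_by_correlation(m)
  top2 <- cutree(hc, 2)
  expect_equal(length(unique(top2[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(top2[c("b1", "b2")])), 1)
  expect_false(top2[["a1"]] == top2[["b1"]])
  # duplicated columns merge first at distance 0
  m2 <- cbind(m, a1copy = m[, "a1"])
  hc2 <- cluster_by_correlation(m2)
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)
  first <- hc2$merge[which.min(hc2$height), ]
  expect_setequal(hc2$labels[-first], c("a1", "a1copy"))
  # distance matrix is symmetric with a zero diagonal
  d <- as.matrix(1 - cor(m))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, ncol(m)))
  expect_error(cluster_by_correlation(cbind(m, flat = rep(1, 300))),
               "constant column")
  nwk <- dendrogram_to_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(colnames(m), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("the SVM predictor is invariant to feature column order", {
  set.seed(40)
  n <- 300
  feat <- matrix(rpois(n * 6, 3), n, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  y <- plogis(rowSums(feat[, 1:3]) / 5 + rnorm(n, 0, 0.5) - 2)
  r1 <- fit_predictor(feat, y, "regression", split_seed = 3)
  r2 <- fit_predictor(feat[, c(4, 2, 6, 1, 3, 5)], y, "regression",
                      split_seed = 3)
  expect_equal(r1$r_prediction, r2$r_prediction, tolerance = 1e-10)
  expect_error(fit_predictor(feat[1:40, ], y[1:40], "regression"),
               "fewer than 50")
})

test_that("the SVM captures a planted interaction that a row sum misses", {
  set.seed(44)
  n <- 2000
  feat <- matrix(rpois(n * 8, 4), n, 8,
                 dimnames = list(NULL, paste0("tf", 1:8)))
  # breadth driven by a nonlinear interaction of two TF columns
  y <- plogis((feat[, 1] - 4) * (feat[, 2] - 4) / 4 + rnorm(n, 0, 0.4))
  rep <- fit_predictor(feat, y, "regression", split_seed = 5)
  r_sum <- abs(correlate(rowSums(feat), y)$r)
  expect_gt(rep$r_prediction, r_sum)
  expect_gt(rep$r_prediction, 0.3)
})

test_that("binary mode reports a cross-validated AUC", {
  set.seed(48)
  n <- 400
  feat <- matrix(rpois(n * 5, 3), n, 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  y <- plogis(rowSums(feat) / 4 + rnorm(n, 0, 0.8) - 4)
  rep <- fit_predictor(feat, y, "binary", split_seed = 2, n_cv = 3)
  expect_true(rep$auc > 0.5 && rep$auc <= 1)
  expect_equal(rep$mode, "binary")
})
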