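test_that("count metrics compute the four variants and ignore peak order", {
  mapping <- data.frame(
    tx_id = c("t1", "t1", "t1", "t2"),
    chrom = "chr1", start = c(0, 5, 10, 0), end = c(4, 9, 14, 4),
    label = c("A", "A", "Pol2", "B"), score = 500L, overlap = 4L,
    stringsAsFactors = FALSE
  )
  cm <- count_metrics(mapping, tx_ids = c("t1", "t2", "t3"))
  expect_equal(cm$tfbs_total, c(3L, 1L, 0L))
  expect_equal(cm$tfbs_unique, c(2L, 1L, 0L))
  expect_equal(cm$tfbs_total_nopol2, c(2L, 1L, 0L))
  expect_equal(cm$tfbs_unique_nopol2, c(1L, 1L, 0L))
  shuffled <- count_metrics(mapping[sample(nrow(mapping)), ],
                            tx_ids = c("t1", "t2", "t3"))
  expect_equal(cm, shuffled)
  # the four counts respect their ordering invariants
  expect_true(all(cm$tfbs_unique <= cm$tfbs_total))
  expect_true(all(cm$tfbs_total_nopol2 <= cm$tfbs_total))
  expect_true(all(cm$tfbs_unique_nopol2 <= cm$tfbs_unique))
})

test_that("total and unique counts are nearly collinear on synthetic data", {
  cfg <- small_config(seed = 31, n_transcripts = 1500)
  ann <- gen_annotation(cfg)
  peaks <- gen_peaks(cfg, ann)
  m <- map_peaks_to_windows(promoter_windows(ann, 500), peaks)
  cm <- count_metrics(m, tx_ids = ann$tx_id)
  expect_gt(correlate(cm$tfbs_total, cm$tfbs_unique)$r, 0.95)
})

test_that("distribution summary follows the five-number-summary hinge rule", {
  s <- summarize_distribution(c(0, 0, 4, 14, 58))
  expect_equal(unname(s$tukey_five), c(0, 0, 4, 14, 58))
  s2 <- summarize_distribution(c(1, 2, 3, 4))
  expect_equal(unname(s2$tukey_five), c(1, 1.5, 2.5, 3.5, 4))
  expect_equal(summarize_distribution(c(1, 2, 6, 7))$pct_le5tf, 50)
  expect_equal(summarize_distribution(c(0, 1, 1, 2, 9))$pct_1tf, 40)
  expect_error(summarize_distribution(numeric(0)), "empty")
  # appending a new maximum raises max and mean, leaves the minimum alone
  x <- rpois(501, 6)
  s3 <- summarize_distribution(x)
  s4 <- summarize_distribution(c(x, max(x) + 1))
  expect_equal(s4$tukey_five[["max"]], s3$tukey_five[["max"]] + 1)
  expect_gt(s4$mean, s3$mean)
  expect_equal(s4$tukey_five[["min"]], s3$tukey_five[["min"]])
  expect_gte(s4$tukey_five[["median"]], s3$tukey_five[["median"]])
})

test_that("sequence composition follows the CpG observed/expected formula", {
  a <- compute_composition("ATAT")
  expect_equal(a$gc, 0); expect_equal(a$cpg_count, 0); expect_equal(a$cpg_oe, 0)
  b <- compute_composition("CGCG")
  expect_equal(b$gc, 1); expect_equal(b$cpg_count, 2); expect_equal(b$cpg_oe, 2)
  c <- compute_composition("ACGT")
  expect_equal(c$gc, 0.5); expect_equal(c$cpg_count, 1); expect_equal(c$cpg_oe, 4)
  # N bases drop out of every denominator
  d <- compute_composition("ANCGN")
  expect_equal(d$gc, 2 / 3); expect_equal(d$cpg_count, 1)
  expect_equal(d$cpg_oe, 3)
  expect_error(compute_composition(""), "empty")
  expect_error(compute_composition("AXGT"), "A, C, G, T, N")
})

test_that("boundary estimator recovers a planted enrichment scale", {
  cfg <- small_config(seed = 41, n_transcripts = 2000,
                      chrom_sizes = c(chr1 = 1.2e8))
  ann <- gen_annotation(cfg)
  peaks <- gen_peaks(cfg, ann)
  be <- estimate_boundary(ann, peaks)
  # within one grid step of the planted 3000 bp scale
  expect_true(be$boundary %in% c(2000, 3000, 4000))
  expect_length(be$derivative, length(be$grid) - 1)
  expect_true(be$boundary %in% be$grid)
  expect_error(estimate_boundary(ann, peaks, grid = c(100, 200)), "at least 5")
  expect_error(estimate_boundary(ann, peaks, grid = c(3, 2, 1, 4, 5)),
               "increasing")
})

test_that("pure background peaks put the boundary at the first grid point", {
  cfg <- small_config(seed = 43, n_transcripts = 800,
                      richness_max = 0, background_rate = 2)
  ann <- gen_annotation(cfg)
  peaks <- gen_peaks(cfg, ann, richness = rep(0L, nrow(ann)))
  be <- estimate_boundary(ann, peaks)
  expect_equal(be$boundary, be$grid[1])
})

test_that("pairwise overlap percentages use the union denominator", {
  same <- data.frame(start = c(0, 0), end = c(10, 10))
  expect_equal(pairwise_overlap_percent(same), 100)
  disjoint <- data.frame(start = c(0, 20), end = c(10, 30))
  expect_equal(pairwise_overlap_percent(disjoint), 0)
  partial <- data.frame(start = c(0, 5), end = c(10, 15))
  expect_equal(pairwise_overlap_percent(partial), 100 * 5 / 15)
  expect_equal(pairwise_overlap_percent(same[1, , drop = FALSE]), numeric(0))
  three <- data.frame(start = c(0, 0, 20), end = c(10, 10, 30))
  expect_length(pairwise_overlap_percent(three), 3)
})

test_that("stacking test flags planted TSS-stacked peaks and is seeded", {
  cfg <- small_config(seed = 51, n_transcripts = 400, stacking_weight = 1)
  ann <- gen_annotation(cfg)
  peaks <- gen_peaks(cfg, ann)
  win <- promoter_windows(ann, 500)
  mp <- map_peaks_to_windows(win, peaks)
  st <- stacking_test(win, mp, seed = 5)
  expect_gt(st$observed_mean_overlap_pct, 2 * st$null_mean_overlap_pct)
  expect_lt(st$p_value, 0.01)
  expect_gte(st$n_pairs, 100)
  st2 <- stacking_test(win, mp, seed = 5)
  expect_identical(st, st2)
  lonely <- mp[!duplicated(mp$tx_id), ]
  expect_error(stacking_test(win, lonely, seed = 1), ">= 2")
})

test_that("generated promoter sequences round-trip composition via FASTA", {
  cfg <- small_config(seed = 55, n_transcripts = 30)
  ann <- gen_annotation(cfg)
  seqs <- gen_promoter_sequences(cfg, ann, width = 400)
  prof <- composition_profiles(seqs)
  expect_equal(nrow(prof), 30)
  expect_true(all(prof$gc > 0.2 & prof$gc < 0.8))
  # realized GC tracks the planted per-transcript fraction
  expect_gt(diff(range(prof$gc)), 0.1)
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  back <- read_promoter_fasta(fa)
  expect_equal(back, seqs)
  expect_equal(composition_profiles(back), prof)
})
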