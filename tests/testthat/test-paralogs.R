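test_that("Jaccard index follows the intersection-over-union definition", {
  expect_equal(jaccard_repertoire(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard_repertoire(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard_repertoire(c("A", "B"), c("B", "C")), 1 / 3)
  # multiplicity is ignored; symmetry holds
  expect_equal(jaccard_repertoire(c("A", "A", "B"), c("B", "A")), 1)
  set.seed(2)
  for (i in 1:25) {
    x <- sample(LETTERS, sample(1:10, 1))
    y <- sample(LETTERS, sample(1:10, 1))
    expect_equal(jaccard_repertoire(x, y), jaccard_repertoire(y, x))
    expect_equal(jaccard_repertoire(x, y) == 1, setequal(x, y))
  }
  empty <- jaccard_repertoire(character(0), character(0))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "both_empty"))
})

test_that("pair enumeration matches the binomial coefficient", {
  expect_equal(nrow(enumerate_all_pairs(letters[1:5])), 10)
  expect_equal(nrow(enumerate_all_pairs(letters[1:10])), 45)
  expect_equal(nrow(enumerate_all_pairs(c("a", "b"))), 1)
  expect_equal(nrow(enumerate_all_pairs("a")), 0)
  for (n in c(2, 3, 7, 20, 50, 200)) {
    p <- enumerate_all_pairs(as.character(seq_len(n)))
    expect_equal(nrow(p), n * (n - 1) / 2)
    expect_false(any(duplicated(paste(pmin(p$gene_x, p$gene_y),
                                      pmax(p$gene_x, p$gene_y)))))
  }
})

test_that("youngest-pair selection keeps each gene's most recent node", {
  # 3-gene family: one old node (age 5) splitting a from {b, c}, one young
  # node (age 1) splitting b from c
  pairs <- data.frame(
    gene_x = c("a", "a", "b"), gene_y = c("b", "c", "c"),
    node = c("n1", "n1", "n2"), age = c(5, 5, 1),
    family_side_x = c(1, 1, 1), family_side_y = c(2, 2, 2)
  )
  kept <- select_youngest_pairs(pairs)
  # b-c is the youngest pair for both daughters; a keeps its only pairs
  expect_true(all(paste(kept$gene_x, kept$gene_y) %in%
                    c("a b", "a c", "b c")))
  expect_true("b c" %in% paste(kept$gene_x, kept$gene_y))
  expect_lte(nrow(kept), nrow(pairs))
  # same-side comparisons are dropped before selection
  ss <- pairs; ss$family_side_y <- ss$family_side_x
  expect_equal(nrow(select_youngest_pairs(ss)), 0)
  na_age <- pairs; na_age$age[2] <- NA
  expect_error(select_youngest_pairs(na_age), "missing age")
})

test_that("every retained pair is youngest for at least one member gene", {
  cfg <- small_config(seed = 71, n_families = 120)
  par <- gen_paralog_families(cfg)
  kept <- select_youngest_pairs(par$pairs)
  min_age <- tapply(c(kept$age, kept$age),
                    c(kept$gene_x, kept$gene_y), min)
  all_min <- tapply(c(par$pairs$age, par$pairs$age),
                    c(par$pairs$gene_x, par$pairs$gene_y), min)
  for (i in seq_len(nrow(kept))) {
    expect_true(kept$age[i] == all_min[[kept$gene_x[i]]] ||
                  kept$age[i] == all_min[[kept$gene_y[i]]])
  }
  # every gene keeps at least one comparison
  expect_setequal(names(min_age), names(all_min))
})

test_that("duplication events classify by the daughters' breadth classes", {
  expect_equal(classify_event("housekeeping", "housekeeping"),
               "housekeeping_conserved")
  expect_equal(classify_event("narrow", "narrow"), "tissue_sp_conserved")
  expect_equal(classify_event("narrow", "housekeeping"), "transformative")
  expect_equal(classify_event("housekeeping", "narrow"), "transformative")
  expect_equal(classify_event("intermediate", "narrow"), "other")
  expect_equal(classify_event("unexpressed", "housekeeping"), "other")
})

test_that("taxon groups map youngest-first and reject unknown taxa", {
  map <- setNames(c("Primate", "Mammalian", "Vertebrate"),
                  c("Homininae", "Theria", "Euteleostomi"))
  g <- assign_taxon_group(c("Theria", "Homininae", "Euteleostomi"), map)
  expect_equal(as.character(g), c("Mammalian", "Primate", "Vertebrate"))
  expect_true(is.ordered(g))
  expect_lt(which(levels(g) == "Primate"), which(levels(g) == "Vertebrate"))
  expect_error(assign_taxon_group("Fungi", map), "Fungi")
})

test_that("age-group summaries report means and Holm-adjusted tests", {
  set.seed(77)
  group <- factor(rep(c("Primate", "Mammalian", "Vertebrate"),
                      times = c(40, 40, 1)),
                  levels = c("Primate", "Mammalian", "Vertebrate"),
                  ordered = TRUE)
  boe <- c(rbeta(40, 2, 8), rbeta(40, 4, 6), 0.5)
  tfbs <- c(rpois(40, 4), rpois(40, 8), 6)
  ags <- age_group_summary(group, boe, tfbs)
  expect_equal(sum(ags$summary$n), 81)
  expect_equal(ags$excluded_groups, "Vertebrate")
  expect_equal(dim(ags$boe_tests), c(1, 1))  # only two testable groups
  # holm-adjusted p is never below the raw p
  raw <- suppressWarnings(
    pairwise.wilcox.test(boe[group != "Vertebrate"],
                         droplevels(group[group != "Vertebrate"]),
                         p.adjust.method = "none"))$p.value
  expect_true(all(ags$boe_tests >= raw - 1e-12, na.rm = TRUE))
})

test_that("divergence analysis recovers planted coupling and its absence", {
  cfg <- small_config(seed = 81, n_families = 250)
  par <- gen_paralog_families(cfg)
  rec <- divergence_records(par$pairs, par$repertoires, par$expression)
  expect_true(all(rec$ji >= 0 & rec$ji <= 1))
  expect_true(all(abs(rec$coexpr) <= 1 + 1e-12))
  res <- divergence_analysis(rec)
  expect_gt(res$r, 0.3)
  expect_lt(res$p, 1e-6)
  # randomized pairing destroys the signal
  set.seed(1)
  rnd <- rec; rnd$coexpr <- sample(rnd$coexpr)
  expect_lt(abs(divergence_analysis(rnd)$r), 0.1)
  # strata restrict to the requested breadth combination
  nn <- divergence_analysis(rec, "both_narrow")
  expect_true(is.na(nn$r) || abs(nn$r) <= 1)
  few <- rec[1:2, ]
  out <- divergence_analysis(few, "both_housekeeping")
  expect_true(out$empty)
  expect_error(divergence_analysis(rec, "nonsense"), "unknown breadth")
})

test_that("paralog tables round-trip with normalized duplicator columns", {
  tab <- data.frame(family = "F1", node = "N1", taxon = "Primate",
                    gene.x = "g1", familySide.x = 1,
                    gene.y = "g2", familySide.y = 2)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_paralog_pairs(path)
  expect_equal(got$gene_x, "g1")
  expect_equal(got$family_side_y, 2)
  bad <- tab; bad$gene.y <- "g1"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_paralog_pairs(path), "self-pair")
})
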