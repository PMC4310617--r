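#' Jaccard index of two promoter TF repertoires
#'
#' `JI = |X intersect Y| / |X union Y|` on sets of distinct TF labels
#' (multiplicity ignored). 1 for identical non-empty repertoires, 0 for
#' disjoint ones; defined as 0 (with attribute `both_empty = TRUE`) when both
#' sets are empty.
#'
#' @param tf_set_x,tf_set_y Character vectors of TF labels.
#' @return Numeric JI in `[0, 1]`.
#' @export
jaccard_repertoire <- function(tf_set_x, tf_set_y) {
  x <- unique(tf_set_x)
  y <- unique(tf_set_y)
  u <- length(union(x, y))
  if (u == 0) {
    ji <- 0
    attr(ji, "both_empty") <- TRUE
    return(ji)
  }
  length(intersect(x, y)) / u
}

#' Enumerate all unordered paralog pairs in a family
#'
#' All `choose(n, 2)` pairs: 10 for a family of five, 45 for a family of
#' ten. Fewer than two members yield an empty table.
#'
#' @param family_members Character vector of gene ids.
#' @return `data.frame` with `gene_x`, `gene_y`.
#' @export
enumerate_all_pairs <- function(family_members) {
  n <- length(family_members)
  if (n < 2)
    return(data.frame(gene_x = character(), gene_y = character(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(n, 2)
  data.frame(gene_x = family_members[idx[1, ]],
             gene_y = family_members[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Select each gene's youngest-pair comparisons
#'
#' Keeps, for each gene, only the pair(s) through its most recent duplication
#' node (the comparison with its closest relative), avoiding
#' pseudo-replication in large families. Pairs whose familySide flags
#' coincide at the defining node (same-side comparisons) are dropped first.
#'
#' @param pairs `data.frame` with `gene_x`, `gene_y`, `node`,
#'   `family_side_x`, `family_side_y`, and `age` (numeric node age; smaller =
#'   younger).
#' @return The retained subset of `pairs`.
#' @export
select_youngest_pairs <- function(pairs) {
  if (any(is.na(pairs$age))) stop("missing age for a duplication node")
  valid <- pairs$family_side_x != pairs$family_side_y
  pairs <- pairs[valid, , drop = FALSE]
  if (nrow(pairs) == 0) return(pairs)
  genes <- c(pairs$gene_x, pairs$gene_y)
  ages <- c(pairs$age, pairs$age)
  min_age <- tapply(ages, genes, min)
  keep <- pairs$age == min_age[pairs$gene_x] |
    pairs$age == min_age[pairs$gene_y]
  pairs[keep, , drop = FALSE]
}

#' Correlate promoter divergence (JI) with paralog co-expression
#'
#' Correlation (Pearson by default) between the per-pair Jaccard index of TF
#' repertoires and the per-pair co-expression coefficient, optionally
#' restricted to a breadth stratum of the two paralogs.
#'
#' @param records `data.frame` with `ji`, `coexpr`, and `breadth_class_x`,
#'   `breadth_class_y` (needed when a stratum is requested).
#' @param breadth_stratum `NULL` (all pairs) or one of `"both_narrow"`,
#'   `"both_intermediate"`, `"both_housekeeping"`,
#'   `"narrow_housekeeping"` (one of each).
#' @param method Correlation type (default `"pearson"`).
#' @return A `correlation_result`, or a list with `empty = TRUE` and the
#'   stratum name when the stratum holds fewer than 3 records.
#' @export
divergence_analysis <- function(records, breadth_stratum = NULL,
                                method = "pearson") {
  if (!is.null(breadth_stratum)) {
    cx <- records$breadth_class_x
    cy <- records$breadth_class_y
    keep <- switch(
      breadth_stratum,
      both_narrow = cx == "narrow" & cy == "narrow",
      both_intermediate = cx == "intermediate" & cy == "intermediate",
      both_housekeeping = cx == "housekeeping" & cy == "housekeeping",
      narrow_housekeeping =
        (cx == "narrow" & cy == "housekeeping") |
        (cx == "housekeeping" & cy == "narrow"),
      stop("unknown breadth stratum: ", breadth_stratum)
    )
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) < 3)
    return(list(empty = TRUE, stratum = breadth_stratum,
                n = nrow(records)))
  correlate(records$ji, records$coexpr, method)
}

#' Classify a duplication event from its daughters' breadth classes
#'
#' `housekeeping_conserved` when both paralogs are housekeeping,
#' `tissue_sp_conserved` when both are narrow (tissue-specific),
#' `transformative` when one is narrow and the other housekeeping, and
#' `other` for any remaining combination (e.g. an intermediate member).
#' Vectorized.
#'
#' @param breadth_class_x,breadth_class_y Classes from [classify_breadth()].
#' @return Character vector of event classes.
#' @export
classify_event <- function(breadth_class_x, breadth_class_y) {
  both_hk <- breadth_class_x == "housekeeping" &
    breadth_class_y == "housekeeping"
  both_ts <- breadth_class_x == "narrow" & breadth_class_y == "narrow"
  transf <- (breadth_class_x == "narrow" &
               breadth_class_y == "housekeeping") |
    (breadth_class_x == "housekeeping" & breadth_class_y == "narrow")
  ifelse(both_hk, "housekeeping_conserved",
         ifelse(both_ts, "tissue_sp_conserved",
                ifelse(transf, "transformative", "other")))
}

#' Assign duplication taxa to mutually exclusive age groups
#'
#' Each duplication maps to exactly one group; the ordered group list runs
#' youngest first (default Primate < Mammalian < Vertebrate < Animal <
#' Eukaryotic) and each group excludes duplications mapping to taxa of
#' preceding (younger) groups by construction of the taxon-to-group map.
#'
#' @param taxa Character vector of duplication taxon labels.
#' @param group_map Named character vector, taxon -> group.
#' @param levels Ordered group levels, youngest first (default
#'   `c("Primate", "Mammalian", "Vertebrate", "Animal", "Eukaryotic")`).
#' @return Factor of groups with the given ordered levels.
#' @export
assign_taxon_group <- function(taxa, group_map,
                               levels = c("Primate", "Mammalian",
                                          "Vertebrate", "Animal",
                                          "Eukaryotic")) {
  g <- unname(group_map[taxa])
  if (any(is.na(g)))
    stop("taxa without a group assignment: ",
         paste(unique(taxa[is.na(g)]), collapse = ", "))
  factor(g, levels = levels, ordered = TRUE)
}

#' Per-age-group summaries of breadth and Tfbs counts, with pairwise tests
#'
#' For each duplication-age group: mean, sd and n of BoE and of TfbsNo, plus
#' all pairwise Wilcoxon rank-sum tests with Holm adjustment. Groups with
#' fewer than 2 records are excluded from the tests and reported.
#'
#' @param group Factor of age groups, one per record.
#' @param boe Numeric BoE per record.
#' @param tfbs_no Numeric Tfbs count per record.
#' @return A list with `summary` (per-group `data.frame`), `boe_tests` and
#'   `tfbs_tests` (Holm-adjusted p-value matrices), and `excluded_groups`.
#' @export
age_group_summary <- function(group, boe, tfbs_no) {
  stopifnot(length(group) == length(boe), length(boe) == length(tfbs_no))
  smry <- data.frame(
    group = levels(group),
    mean_boe = as.numeric(tapply(boe, group, mean)),
    sd_boe = as.numeric(tapply(boe, group, stats::sd)),
    mean_tfbs = as.numeric(tapply(tfbs_no, group, mean)),
    sd_tfbs = as.numeric(tapply(tfbs_no, group, stats::sd)),
    n = as.integer(table(group)),
    stringsAsFactors = FALSE
  )
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  ok <- !(as.character(group) %in% small)
  g <- droplevels(factor(group[ok], levels = levels(group)))
  test <- function(v) {
    suppressWarnings(
      stats::pairwise.wilcox.test(v, g, p.adjust.method = "holm"))$p.value
  }
  list(
    summary = smry,
    boe_tests = if (nlevels(g) >= 2) test(boe[ok]) else NULL,
    tfbs_tests = if (nlevels(g) >= 2) test(tfbs_no[ok]) else NULL,
    excluded_groups = small
  )
}

#' Read a paralog-pair table
#'
#' Tab-delimited with the denormalized duplication-pair columns: `family`,
#' `node`, `taxon`, `gene.x`, `familySide.x`, `gene.y`, `familySide.y`
#' (extra columns preserved). Column names are normalized to `gene_x`,
#' `family_side_x`, etc.
#'
#' @param path Path to the file.
#' @return `data.frame` of paralog pairs.
#' @export
read_paralog_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- gsub(".", "_", names(tab), fixed = TRUE)
  names(tab) <- sub("^familySide", "family_side", names(tab))
  need <- c("family", "node", "taxon", "gene_x", "family_side_x",
            "gene_y", "family_side_y")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("paralog table lacks columns: ", paste(miss, collapse = ", "))
  if (any(tab$gene_x == tab$gene_y)) stop("self-pair in paralog table")
  tab
}

#' Build per-pair divergence records
#'
#' Joins a paralog-pair table with per-gene TF repertoires and a TPM
#' expression matrix into the per-pair analysis record: Jaccard index of the
#' two repertoires, co-expression across samples, per-gene BoE and breadth
#' class, Tfbs counts, and the duplication event class.
#'
#' @param pairs Paralog-pair table (`gene_x`, `gene_y`, plus any node/taxon
#'   columns, which are carried through).
#' @param repertoires Named list of TF label sets per gene.
#' @param expression TPM matrix with genes as rownames.
#' @param cutoff_tpm 'On' cutoff for BoE (default 10).
#' @param coexpr_method Correlation for co-expression (default `"pearson"`).
#' @return `data.frame` of records: the input columns plus `ji`, `coexpr`,
#'   `boe_x`, `boe_y`, `tfbs_x`, `tfbs_y`, `breadth_class_x`,
#'   `breadth_class_y`, `event_class`.
#' @export
divergence_records <- function(pairs, repertoires, expression,
                               cutoff_tpm = 10, coexpr_method = "pearson") {
  gx <- pairs$gene_x; gy <- pairs$gene_y
  miss <- setdiff(unique(c(gx, gy)),
                  intersect(names(repertoires), rownames(expression)))
  if (length(miss) > 0)
    stop("genes lacking repertoire or expression: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- pairs
  out$ji <- vapply(seq_along(gx), function(i) {
    as.numeric(jaccard_repertoire(repertoires[[gx[i]]],
                                  repertoires[[gy[i]]]))
  }, numeric(1))
  ex <- expression[gx, , drop = FALSE]
  ey <- expression[gy, , drop = FALSE]
  out$coexpr <- vapply(seq_along(gx), function(i) {
    stats::cor(ex[i, ], ey[i, ], method = coexpr_method)
  }, numeric(1))
  out$boe_x <- breadth(ex, cutoff_tpm)
  out$boe_y <- breadth(ey, cutoff_tpm)
  out$tfbs_x <- vapply(repertoires[gx], length, integer(1))
  out$tfbs_y <- vapply(repertoires[gy], length, integer(1))
  out$breadth_class_x <- classify_breadth(out$boe_x)
  out$breadth_class_y <- classify_breadth(out$boe_y)
  out$event_class <- classify_event(out$breadth_class_x,
                                    out$breadth_class_y)
  rownames(out) <- NULL
  out
}
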