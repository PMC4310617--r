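#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators. The defaults emulate the
#' structure of clustered ChIP-seq peak sets around RefSeq-like TSSs with
#' CAGE-style TPM expression: a heavy-tailed per-transcript binding-site
#' intensity (discrete power law truncated at `richness_max`), TSS-proximal
#' peak enrichment decaying to a uniform background beyond
#' `enrichment_scale`, a fraction of peaks "stacked" at the TSS, a monotone
#' noisy link from binding-site richness to expression breadth, and paralog
#' families whose promoter-repertoire Jaccard index and co-expression both
#' decay with duplication age.
#'
#' @param seed Integer master seed (all generators are deterministic given
#'   the config).
#' @param n_transcripts Number of transcripts (default 10000).
#' @param n_samples Named vector of samples per class (default 179 tissues).
#' @param chrom_sizes Named chromosome lengths (default one 600 Mb
#'   chromosome).
#' @param tss_spacing Minimum TSS spacing in bases (default 20000,
#'   keeping even the widest analysis windows of neighboring promoters
#'   disjoint).
#' @param richness_alpha Exponent of the truncated discrete power law
#'   `P(k) ~ (k + 1)^-alpha`, `k = 0..richness_max` (default 1.05, giving a
#'   median near 4).
#' @param richness_max Truncation of the count law (default 60).
#' @param enrichment_scale Distance over which TSS-proximal peak density
#'   decays (linearly) to the background rate, in bases (default 3000).
#' @param background_rate Background peaks per kb of genome (default 0.05).
#' @param stacking_weight Fraction of proximal peaks placed centered at the
#'   TSS mode (default 0.15).
#' @param peak_length_mean,peak_length_sd Peak length distribution in bases
#'   (defaults 250 and 60, floored at 50).
#' @param n_tf_labels Size of the TF label pool, including the
#'   polymerase-class labels Pol2, Pol3 and TAF1 (default 148).
#' @param breadth_link Coefficients of the logistic richness-to-breadth link
#'   `p_on = plogis(b0 + b1 * log1p(richness) + N(0, sigma))`
#'   (default `list(b0 = -2.8, b1 = 0.8, sigma = 1.6)`, calibrated once so
#'   the realized correlation between mapped Tfbs counts and BoE sits at the
#'   planted target of about 0.45 under the default profiling thresholds).
#' @param on_tpm_meanlog,on_tpm_sdlog Log-normal magnitude (added above the
#'   10 TPM floor) for 'on' samples (defaults 0.5, 1).
#' @param off_tpm_mean Mean of the sub-threshold exponential TPM for 'off'
#'   samples, capped below 10 (default 3).
#' @param n_families Number of paralog families (default 500).
#' @param family_size_geom Geometric parameter; family size =
#'   `2 + rgeom(p)` (default 0.45).
#' @param age_levels Ordered duplication-age labels, youngest first.
#' @param age_weights Sampling weights of duplication ages.
#' @param ji_retention Per-age per-label retention probability at a
#'   duplication (youngest first; higher = less promoter divergence).
#' @param coexpr_rho Per-age latent-expression correlation across a
#'   duplication (youngest first).
#' @param age_boe Planted mean BoE by the age of a gene's most recent
#'   duplication (youngest first, monotone increasing).
#' @param age_gain Mean count of newly gained repertoire labels per daughter
#'   at a duplication of each age (youngest first, increasing: older
#'   duplicates accumulate more binding sites, so the age trend in Tfbs
#'   counts is planted through net repertoire gain).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_transcripts = 10000,
                             n_samples = c(tissue = 179),
                             chrom_sizes = c(chr1 = 6e8),
                             tss_spacing = 20000,
                             richness_alpha = 1.05,
                             richness_max = 60,
                             enrichment_scale = 3000,
                             background_rate = 0.05,
                             stacking_weight = 0.15,
                             peak_length_mean = 250,
                             peak_length_sd = 60,
                             n_tf_labels = 148,
                             breadth_link = list(b0 = -2.8, b1 = 0.8,
                                                 sigma = 1.6),
                             on_tpm_meanlog = 0.5,
                             on_tpm_sdlog = 1,
                             off_tpm_mean = 3,
                             n_families = 500,
                             family_size_geom = 0.45,
                             age_levels = c("Primate", "Mammalian",
                                            "Vertebrate", "Animal",
                                            "Eukaryotic"),
                             age_weights = c(0.07, 0.11, 0.42, 0.35, 0.05),
                             ji_retention = c(0.95, 0.85, 0.70, 0.55, 0.40),
                             coexpr_rho = c(0.90, 0.75, 0.60, 0.45, 0.30),
                             age_boe = c(0.10, 0.15, 0.22, 0.28, 0.35),
                             age_gain = c(0, 2, 4, 7, 10)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_transcripts > 0, all(cfg$chrom_sizes > 0),
            cfg$stacking_weight >= 0, cfg$stacking_weight <= 1,
            cfg$background_rate >= 0, cfg$enrichment_scale > 0,
            length(cfg$ji_retention) == length(cfg$age_levels),
            length(cfg$coexpr_rho) == length(cfg$age_levels),
            length(cfg$age_boe) == length(cfg$age_levels),
            length(cfg$age_gain) == length(cfg$age_levels))
  class(cfg) <- "synthetic_config"
  cfg
}

# TF label pool; the polymerase-class labels come first and get the largest
# Zipf weights, mirroring their ubiquity in clustered ChIP-seq peak sets.
tf_label_pool <- function(config) {
  n <- config$n_tf_labels
  labels <- c("Pol2", "TAF1", "Pol3",
              sprintf("TF%03d", seq_len(max(0, n - 3))))[seq_len(n)]
  w <- 1 / seq_len(n)^0.7
  list(labels = labels, weights = w / sum(w))
}

#' Draw per-transcript binding-site richness
#'
#' The latent heavy-tailed intensity: a discrete power law
#' `P(k) ~ (k + 1)^-alpha` truncated at `richness_max`.
#'
#' @param config A [synthetic_config()].
#' @param n Number of draws (default `config$n_transcripts`).
#' @return Integer vector of richness values in `0..richness_max`.
#' @export
draw_richness <- function(config, n = config$n_transcripts) {
  set.seed(config$seed + 101L)
  k <- 0:config$richness_max
  if (length(k) == 1) return(rep(k, n))
  p <- (k + 1)^(-config$richness_alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Generate transcript annotations
#'
#' TSSs are placed uniformly per chromosome with a minimum pairwise spacing
#' (by jittering a regular grid); strands are random 50/50.
#'
#' @param config A [synthetic_config()].
#' @return Annotation `data.frame` (`tx_id`, `chrom`, `strand`, `tss`).
#' @export
gen_annotation <- function(config) {
  set.seed(config$seed + 1L)
  sizes <- config$chrom_sizes
  n <- config$n_transcripts
  # allocate transcripts to chromosomes proportional to length
  alloc <- diff(round(c(0, cumsum(sizes) / sum(sizes) * n)))
  out <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    m <- alloc[ci]
    if (m == 0) next
    slot <- sizes[ci] / m
    if (slot < config$tss_spacing + 1)
      stop("infeasible TSS spacing for ", names(sizes)[ci])
    jitter_room <- slot - config$tss_spacing
    tss <- floor((seq_len(m) - 1) * slot + config$tss_spacing / 2 +
                   stats::runif(m, 0, jitter_room))
    out[[ci]] <- data.frame(
      chrom = names(sizes)[ci],
      tss = as.integer(tss),
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, out)
  ann$tx_id <- sprintf("TX%06d", seq_len(nrow(ann)))
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  ann[, c("tx_id", "chrom", "strand", "tss")]
}

#' Generate synthetic ChIP-seq-like peaks
#'
#' Per transcript, `richness` proximal peaks are placed around the TSS: a
#' fraction `stacking_weight` centered exactly at the TSS (the stacked mode)
#' and the rest at offsets `sign * enrichment_scale * Beta(1, 2)` so the
#' proximal density decays linearly to zero at `enrichment_scale`. Uniform
#' background peaks are added at `background_rate` per kb. TF labels are
#' drawn from a Zipf-weighted pool (polymerase-class labels most common);
#' scores are uniform integers in 0--1000.
#'
#' @param config A [synthetic_config()].
#' @param annotations Annotations from [gen_annotation()].
#' @param richness Optional per-transcript richness; drawn via
#'   [draw_richness()] when `NULL`.
#' @return Peak interval `data.frame` (BED6 columns).
#' @export
gen_peaks <- function(config, annotations, richness = NULL) {
  if (is.null(richness)) richness <- draw_richness(config)
  stopifnot(length(richness) == nrow(annotations))
  set.seed(config$seed + 2L)
  pool <- tf_label_pool(config)
  sizes <- config$chrom_sizes

  n_prox <- sum(richness)
  tx_idx <- rep(seq_len(nrow(annotations)), richness)
  stacked <- stats::runif(n_prox) < config$stacking_weight
  mag <- config$enrichment_scale * stats::rbeta(n_prox, 1, 2)
  offset <- ifelse(stacked, 0,
                   round(mag * sample(c(-1, 1), n_prox, replace = TRUE)))
  len <- pmax(50, round(stats::rnorm(n_prox, config$peak_length_mean,
                                     config$peak_length_sd)))
  center <- annotations$tss[tx_idx] + offset
  start <- center - floor(len / 2)
  end <- start + len
  chrom <- annotations$chrom[tx_idx]

  n_bg <- stats::rpois(1, config$background_rate * sum(sizes) / 1000)
  if (n_bg > 0) {
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
    bg_len <- pmax(50, round(stats::rnorm(n_bg, config$peak_length_mean,
                                          config$peak_length_sd)))
    bg_start <- floor(stats::runif(n_bg) *
                        (unname(sizes[bg_chrom]) - bg_len))
    chrom <- c(chrom, bg_chrom)
    start <- c(start, bg_start)
    end <- c(end, bg_start + bg_len)
  }
  n_all <- length(chrom)
  lim <- unname(sizes[chrom])
  start <- pmax(0L, as.integer(start))
  end <- pmin(lim, as.integer(end))
  keep <- start < end
  genomic_intervals(
    chrom = chrom[keep],
    start = start[keep],
    end = end[keep],
    strand = ".",
    score = sample(0:1000, n_all, replace = TRUE)[keep],
    label = sample(pool$labels, n_all, replace = TRUE,
                   prob = pool$weights)[keep]
  )
}

#' Generate a synthetic TPM expression table
#'
#' Each transcript's per-sample 'on' indicator is Bernoulli with probability
#' `plogis(b0 + b1 * log1p(richness) + N(0, sigma))` - the planted monotone
#' noisy coupling between binding-site richness and expression breadth. 'On'
#' samples get TPM `10 + lognormal` (always above the 10 TPM cutoff); 'off'
#' samples get sub-threshold exponential TPM capped below 10.
#'
#' @param config A [synthetic_config()].
#' @param annotations Annotations from [gen_annotation()].
#' @param richness Per-transcript richness aligned to `annotations`.
#' @return An expression table (see [expression_table()]).
#' @export
gen_expression <- function(config, annotations, richness) {
  stopifnot(length(richness) == nrow(annotations))
  set.seed(config$seed + 3L)
  n <- nrow(annotations)
  ns <- sum(config$n_samples)
  bl <- config$breadth_link
  p_on <- stats::plogis(bl$b0 + bl$b1 * log1p(richness) +
                          stats::rnorm(n, 0, bl$sigma))
  on <- matrix(stats::runif(n * ns) < rep(p_on, ns), nrow = n)
  v <- matrix(pmin(stats::rexp(n * ns, 1 / config$off_tpm_mean), 9.99),
              nrow = n)
  n_on <- sum(on)
  v[on] <- 10 + stats::rlnorm(n_on, config$on_tpm_meanlog,
                              config$on_tpm_sdlog)
  cls <- rep(names(config$n_samples), config$n_samples)
  rownames(v) <- annotations$tx_id
  colnames(v) <- sprintf("%s_%03d", cls, stats::ave(seq_len(ns), cls,
                                                    FUN = seq_along))
  expression_table(v, cls)
}

#' Generate paralog families with planted age-coupled divergence
#'
#' Each family grows by sequential duplication of a random lineage; the
#' duplication events get age levels sampled by `age_weights` and sorted
#' oldest-first. Across a duplication of age `a`, each daughter keeps each
#' repertoire label with probability `ji_retention[a]` (lost labels are not
#' replaced) and gains `Pois(age_gain[a])` new labels, so
#' pair Jaccard indexes decay with node age while older duplicates
#' accumulate larger repertoires. Latent expression evolves as
#' `z' = sqrt(rho_a) z + sqrt(1 - rho_a) N(0, 1)` per sample, so
#' co-expression also decays with node age. A gene's breadth target follows
#' `age_boe` at the age of its most recent duplication (young duplicates are
#' more tissue-specific); its TPM row is a lognormal transform of the latent
#' vector thresholded to hit that target breadth.
#'
#' @param config A [synthetic_config()].
#' @return A list with `pairs` (family, node, taxon, age, gene/side columns
#'   for every within-family pair at its defining duplication node),
#'   `repertoires` (named list of TF label sets per gene), and `expression`
#'   (TPM matrix, genes x samples).
#' @export
gen_paralog_families <- function(config) {
  set.seed(config$seed + 4L)
  pool <- tf_label_pool(config)
  ns <- sum(config$n_samples)
  n_ages <- length(config$age_levels)
  all_pairs <- list()
  repertoires <- list()
  expr_rows <- list()

  mutate_repertoire <- function(rep0, age) {
    keep <- stats::runif(length(rep0)) < config$ji_retention[age]
    gained <- stats::rpois(1, config$age_gain[age])
    unique(c(rep0[keep],
             sample(pool$labels, gained, replace = TRUE,
                    prob = pool$weights)))
  }
  mutate_latent <- function(z, age) {
    r <- config$coexpr_rho[age]
    sqrt(r) * z + sqrt(1 - r) * stats::rnorm(length(z))
  }

  for (f in seq_len(config$n_families)) {
    m <- 2 + stats::rgeom(1, config$family_size_geom)
    event_ages <- sort(sample(seq_len(n_ages), m - 1, replace = TRUE,
                              prob = config$age_weights), decreasing = TRUE)
    root_size <- 1 + stats::rpois(1, 4.5)
    leaves <- list(list(
      rep = unique(sample(pool$labels, root_size, replace = TRUE,
                          prob = pool$weights)),
      z = stats::rnorm(ns),
      path_nodes = integer(0),
      path_sides = integer(0),
      youngest = NA_integer_
    ))
    for (e in seq_len(m - 1)) {
      age <- event_ages[e]
      gi <- sample.int(length(leaves), 1)
      parent <- leaves[[gi]]
      mk <- function(side) {
        list(rep = mutate_repertoire(parent$rep, age),
             z = mutate_latent(parent$z, age),
             path_nodes = c(parent$path_nodes, e),
             path_sides = c(parent$path_sides, side),
             youngest = age)
      }
      leaves[[gi]] <- mk(1L)
      leaves[[length(leaves) + 1L]] <- mk(2L)
    }
    gene_ids <- sprintf("F%04dG%02d", f, seq_along(leaves))
    # expression rows: threshold latent z so breadth matches the age target
    for (gi in seq_along(leaves)) {
      lf <- leaves[[gi]]
      age <- if (is.na(lf$youngest)) n_ages else lf$youngest
      target <- stats::plogis(stats::qlogis(config$age_boe[age]) +
                                stats::rnorm(1, 0, 0.6))
      thr <- stats::quantile(lf$z, 1 - target)
      expr_rows[[gene_ids[gi]]] <- 10 * exp(lf$z - thr)
      repertoires[[gene_ids[gi]]] <- lf$rep
    }
    # all within-family pairs, each at its defining (MRCA) node
    if (length(leaves) >= 2) {
      idx <- utils::combn(length(leaves), 2)
      fam_pairs <- lapply(seq_len(ncol(idx)), function(k) {
        a <- leaves[[idx[1, k]]]; b <- leaves[[idx[2, k]]]
        common <- intersect(a$path_nodes, b$path_nodes)
        # the MRCA is the deepest shared node where the sides differ
        sa <- a$path_sides[match(common, a$path_nodes)]
        sb <- b$path_sides[match(common, b$path_nodes)]
        node <- max(common[sa != sb])
        data.frame(
          family = sprintf("F%04d", f),
          node = sprintf("F%04dN%02d", f, node),
          taxon = config$age_levels[event_ages[node]],
          age = event_ages[node],
          gene_x = gene_ids[idx[1, k]],
          family_side_x = a$path_sides[match(node, a$path_nodes)],
          gene_y = gene_ids[idx[2, k]],
          family_side_y = b$path_sides[match(node, b$path_nodes)],
          stringsAsFactors = FALSE
        )
      })
      all_pairs[[f]] <- do.call(rbind, fam_pairs)
    }
  }
  expression <- do.call(rbind, expr_rows)
  colnames(expression) <- sprintf("sample_%03d", seq_len(ns))
  list(
    pairs = do.call(rbind, all_pairs),
    repertoires = repertoires,
    expression = expression
  )
}

#' Generate a full synthetic dataset
#'
#' Orchestrates [gen_annotation()], [draw_richness()], [gen_peaks()],
#' [gen_expression()] and [gen_paralog_families()] under one config.
#'
#' @param config A [synthetic_config()].
#' @param paralogs Also generate paralog families (default TRUE).
#' @return A list with `config`, `annotations`, `richness`, `peaks`,
#'   `expression`, and (optionally) `paralogs`.
#' @export
simulate_dataset <- function(config = synthetic_config(), paralogs = TRUE) {
  annotations <- gen_annotation(config)
  richness <- draw_richness(config)
  peaks <- gen_peaks(config, annotations, richness)
  expression <- gen_expression(config, annotations, richness)
  out <- list(config = config, annotations = annotations,
              richness = richness, peaks = peaks, expression = expression)
  if (paralogs) out$paralogs <- gen_paralog_families(config)
  out
}

#' Generate random promoter sequences
#'
#' Independent per-base draws with a per-transcript GC fraction uniform on
#' `gc_range`; a plain source of composition covariates (no motif
#' structure).
#'
#' @param config A [synthetic_config()].
#' @param annotations Annotations from [gen_annotation()].
#' @param width Sequence length in bases (default twice the 500 bp
#'   half-width).
#' @param gc_range GC-fraction range (default `c(0.35, 0.65)`).
#' @return Named character vector of sequences, one per transcript.
#' @export
gen_promoter_sequences <- function(config, annotations, width = 1000,
                                   gc_range = c(0.35, 0.65)) {
  set.seed(config$seed + 5L)
  n <- nrow(annotations)
  gc <- stats::runif(n, gc_range[1], gc_range[2])
  seqs <- vapply(gc, function(g) {
    paste(sample(c("A", "T", "C", "G"), width, replace = TRUE,
                 prob = c((1 - g) / 2, (1 - g) / 2, g / 2, g / 2)),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, annotations$tx_id)
}
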