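#' Default run configuration
#'
#' Thresholds default to the study conventions: ±500 bp promoter windows,
#' peak-score cutoff 500, 'on' TPM cutoffs 10/100/1000, breadth 0.33 /
#' Tfbs-count 10 class boundaries, 1000 permutation replicates.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    inputs = list(peaks = NULL, annotations = NULL, expression = NULL,
                  paralog_pairs = NULL, repertoires = NULL),
    window_half_width = 500,
    score_cutoff = 500,
    tpm_cutoffs = c(10, 100, 1000),
    pol2_labels = c("Pol2", "POLR2A", "Pol2-4H8", "Pol3"),
    n_reps = 1000,
    seed = 1,
    boe_broad_cutoff = 0.33,
    tfbs_rich_cutoff = 10,
    boundary_grid = c(250, 500, 1000, 2000, 3000, 4000, 5000, 7500, 10000),
    synthetic = list()
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$window_half_width <= 0) stop("invalid config value: window_half_width")
  if (cfg$score_cutoff < 0 || cfg$score_cutoff > 1000)
    stop("invalid config value: score_cutoff")
  if (any(cfg$tpm_cutoffs < 0)) stop("invalid config value: tpm_cutoffs")
  if (cfg$n_reps < 1) stop("invalid config value: n_reps")
  if (cfg$boe_broad_cutoff < 0 || cfg$boe_broad_cutoff > 1)
    stop("invalid config value: boe_broad_cutoff")
  if (length(cfg$boundary_grid) < 5 || any(diff(cfg$boundary_grid) <= 0))
    stop("invalid config value: boundary_grid")
  invisible(cfg)
}

#' Load a run configuration from JSON or YAML
#'
#' Absent fields take their defaults; unknown fields are rejected by name.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    if (file.info(path)$size == 0) list() else
      jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("config must be .json, .yaml or .yml: ", path)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    if (nm == "inputs") {
      bad <- setdiff(names(raw$inputs), names(cfg$inputs))
      if (length(bad) > 0)
        stop("unknown config field(s): ",
             paste0("inputs.", bad, collapse = ", "))
      # index assignment keeps keys whose configured value is null
      cfg$inputs[names(raw$inputs)] <- raw$inputs
    } else if (nm == "synthetic") {
      cfg$synthetic[names(raw$synthetic)] <- raw$synthetic
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_run_config(cfg)
  cfg
}

#' Save a run configuration as JSON
#'
#' @param cfg A `run_config`.
#' @param path Output path (`.json`).
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialized config, for the
# run manifest fingerprint.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(out_dir, subcommand, cfg, inputs = list()) {
  manifest <- list(
    subcommand = subcommand,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    inputs = inputs,
    package_version = as.character(utils::packageVersion("promarch")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

require_input <- function(cfg, name) {
  p <- cfg$inputs[[name]]
  if (is.null(p) || !file.exists(p))
    stop("missing input '", name, "': ",
         if (is.null(p)) "not configured" else p)
  p
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis end-to-end on files: `simulate` writes a
#' synthetic dataset; `profile` maps peaks to promoter windows and writes
#' the per-transcript architecture profile; `breadth` writes the
#' per-transcript expression summary; `associate` correlates Tfbs count with
#' BoE including the promoter-shuffle permutation null; `boundary` runs the
#' effective-promoter-size estimator; `stacking` runs the peak-stacking
#' randomization test; `paralogs` builds divergence records and the
#' age-group summary; `predict` fits the SVM breadth predictor. Every stage
#' writes a `manifest.json` (inputs, config hash, seed, versions) beside its
#' outputs and never mutates its inputs.
#'
#' @param subcommand One of `simulate`, `profile`, `breadth`, `associate`,
#'   `boundary`, `stacking`, `paralogs`, `predict`.
#' @param config A `run_config` (see [default_run_config()],
#'   [load_run_config()]). Stages after `simulate` read the file paths in
#'   `config$inputs`; after a `simulate` into the same directory those
#'   default to the simulated files.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
run_stage <- function(subcommand, config = default_run_config(),
                      out_dir = ".") {
  subcommand <- match.arg(subcommand,
                          c("simulate", "profile", "breadth", "associate",
                            "boundary", "stacking", "paralogs", "predict"))
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(
    subcommand,
    simulate = stage_simulate(config, out_dir),
    profile = stage_profile(config, out_dir),
    breadth = stage_breadth(config, out_dir),
    associate = stage_associate(config, out_dir),
    boundary = stage_boundary(config, out_dir),
    stacking = stage_stacking(config, out_dir),
    paralogs = stage_paralogs(config, out_dir),
    predict = stage_predict(config, out_dir)
  )
  write_manifest(out_dir, subcommand, config,
                 inputs = Filter(Negate(is.null), config$inputs))
  invisible(paths)
}

#' Point a run config at the files of a simulate stage
#'
#' @param config A `run_config`.
#' @param dir Directory written by `run_stage("simulate", ...)`.
#' @return The config with `inputs` filled in.
#' @export
use_simulated_inputs <- function(config, dir) {
  config$inputs <- list(
    peaks = file.path(dir, "peaks.bed"),
    annotations = file.path(dir, "annotations.bed"),
    expression = file.path(dir, "expression.tsv"),
    paralog_pairs = file.path(dir, "paralog_pairs.tsv"),
    repertoires = file.path(dir, "repertoires.tsv")
  )
  config
}

synthetic_config_from <- function(config) {
  do.call(synthetic_config,
          utils::modifyList(list(seed = config$seed), config$synthetic))
}

stage_simulate <- function(config, out_dir) {
  ds <- simulate_dataset(synthetic_config_from(config))
  ann <- ds$annotations
  ann_bed <- genomic_intervals(
    chrom = ann$chrom,
    start = ifelse(ann$strand == "+", ann$tss, ann$tss - 1L),
    end = ifelse(ann$strand == "+", ann$tss + 1L, ann$tss),
    strand = ann$strand, score = 0L, label = ann$tx_id
  )
  p <- list(
    peaks = file.path(out_dir, "peaks.bed"),
    annotations = file.path(out_dir, "annotations.bed"),
    expression = file.path(out_dir, "expression.tsv"),
    richness = file.path(out_dir, "richness.tsv"),
    paralog_pairs = file.path(out_dir, "paralog_pairs.tsv"),
    repertoires = file.path(out_dir, "repertoires.tsv"),
    paralog_expression = file.path(out_dir, "paralog_expression.tsv")
  )
  write_bed(ds$peaks, p$peaks)
  write_bed(ann_bed, p$annotations)
  write_expression_table(ds$expression, p$expression,
                         comment = "synthetic TPM expression table")
  utils::write.table(data.frame(tx_id = ann$tx_id, richness = ds$richness),
                     p$richness, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$paralogs$pairs, p$paralog_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reps <- ds$paralogs$repertoires
  utils::write.table(
    data.frame(gene = rep(names(reps), lengths(reps)),
               label = unlist(reps, use.names = FALSE)),
    p$repertoires, sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_table(
    expression_table(ds$paralogs$expression),
    p$paralog_expression, comment = "synthetic paralog TPM table")
  p
}

read_inputs_pa <- function(config) {
  peaks <- parse_bed(require_input(config, "peaks"))
  ann <- annotation_from_bed(parse_bed(require_input(config, "annotations")))
  list(peaks = peaks, annotations = ann)
}

stage_profile <- function(config, out_dir) {
  io <- read_inputs_pa(config)
  peaks <- filter_by_score(io$peaks, config$score_cutoff)
  windows <- promoter_windows(io$annotations, config$window_half_width)
  mapping <- map_peaks_to_windows(windows, peaks)
  profile <- count_metrics(mapping, tx_ids = io$annotations$tx_id,
                           pol2_labels = config$pol2_labels)
  p <- list(profile = file.path(out_dir, "architecture_profile.tsv"),
            distribution = file.path(out_dir, "count_distribution.json"))
  utils::write.table(profile, p$profile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_json_report(summarize_distribution(profile$tfbs_total),
                    p$distribution)
  p
}

stage_breadth <- function(config, out_dir) {
  expr <- read_expression_table(require_input(config, "expression"))
  smry <- expression_summary(expr, config$tpm_cutoffs)
  p <- list(summary = file.path(out_dir, "expression_summary.tsv"))
  utils::write.table(smry, p$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}

profile_and_breadth <- function(config) {
  io <- read_inputs_pa(config)
  peaks <- filter_by_score(io$peaks, config$score_cutoff)
  windows <- promoter_windows(io$annotations, config$window_half_width)
  mapping <- map_peaks_to_windows(windows, peaks)
  profile <- count_metrics(mapping, tx_ids = io$annotations$tx_id,
                           pol2_labels = config$pol2_labels)
  expr <- read_expression_table(require_input(config, "expression"))
  boe <- breadth(expr$values, config$tpm_cutoffs[1])
  merged <- merge(profile,
                  data.frame(tx_id = expr$tx_ids, boe = boe,
                             stringsAsFactors = FALSE),
                  by = "tx_id")
  list(mapping = mapping, windows = windows, profile = profile,
       expr = expr, merged = merged)
}

stage_associate <- function(config, out_dir) {
  pb <- profile_and_breadth(config)
  if (stats::sd(pb$merged$tfbs_total) == 0)
    stop("constant column: tfbs_total (no variation at this cutoff)")
  corr <- correlate(pb$merged$tfbs_total, pb$merged$boe, "pearson")
  null <- shuffle_null(pb$merged$tfbs_total, pb$merged$boe,
                       n_reps = config$n_reps, seed = config$seed)
  report <- list(
    n = corr$n,
    r_tfbs_boe = corr$r, t = corr$t, df = corr$df, p = corr$p,
    null_mean_t = mean(null$replicates),
    empirical_p = null$empirical_p,
    n_reps = null$n_reps
  )
  p <- list(report = file.path(out_dir, "association.json"))
  write_json_report(report, p$report)
  p
}

stage_boundary <- function(config, out_dir) {
  io <- read_inputs_pa(config)
  peaks <- filter_by_score(io$peaks, config$score_cutoff)
  be <- estimate_boundary(io$annotations, peaks, grid = config$boundary_grid)
  p <- list(boundary = file.path(out_dir, "boundary.json"),
            curve = file.path(out_dir, "boundary_curve.tsv"))
  write_json_report(list(boundary = be$boundary), p$boundary)
  utils::write.table(
    data.frame(half_width = be$grid, mean_count = be$mean_counts,
               smoothed = be$smoothed),
    p$curve, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stage_stacking <- function(config, out_dir) {
  io <- read_inputs_pa(config)
  peaks <- filter_by_score(io$peaks, config$score_cutoff)
  windows <- promoter_windows(io$annotations, config$window_half_width)
  mapping <- map_peaks_to_windows(windows, peaks)
  st <- stacking_test(windows, mapping, n_randomizations = 1,
                      seed = config$seed)
  p <- list(stacking = file.path(out_dir, "stacking.json"))
  write_json_report(st, p$stacking)
  p
}

stage_paralogs <- function(config, out_dir) {
  pairs <- read_paralog_pairs(require_input(config, "paralog_pairs"))
  reps_tab <- utils::read.table(require_input(config, "repertoires"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  repertoires <- split(reps_tab$label, reps_tab$gene)
  pexpr_path <- file.path(dirname(require_input(config, "paralog_pairs")),
                          "paralog_expression.tsv")
  expr <- read_expression_table(pexpr_path)
  records <- divergence_records(pairs, repertoires, expr$values,
                                cutoff_tpm = config$tpm_cutoffs[1])
  corr <- divergence_analysis(records)
  youngest <- select_youngest_pairs(records)
  grp <- assign_taxon_group(records$taxon,
                            stats::setNames(levels(factor(records$taxon)),
                                            levels(factor(records$taxon))))
  ags <- age_group_summary(grp, (records$boe_x + records$boe_y) / 2,
                           (records$tfbs_x + records$tfbs_y) / 2)
  p <- list(records = file.path(out_dir, "divergence_records.tsv"),
            youngest = file.path(out_dir, "youngest_pairs.tsv"),
            report = file.path(out_dir, "paralogs.json"))
  utils::write.table(records, p$records, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(youngest, p$youngest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_json_report(list(
    r_ji_coexpr = corr$r, t = corr$t, p = corr$p, n = corr$n,
    n_youngest = nrow(youngest),
    age_groups = ags$summary,
    event_classes = as.list(table(records$event_class))
  ), p$report)
  p
}

stage_predict <- function(config, out_dir) {
  pb <- profile_and_breadth(config)
  feat <- tf_count_matrix(pb$mapping, tx_ids = pb$merged$tx_id)
  rep <- fit_predictor(feat, pb$merged$boe, mode = "regression",
                       split_seed = config$seed)
  p <- list(report = file.path(out_dir, "predictor.json"))
  write_json_report(list(
    mode = rep$mode, r_prediction = rep$r_prediction,
    r_scrambled = rep$r_scrambled, r_retained = rep$r_retained,
    split_seed = rep$split_seed, hyperparameters = rep$hyperparameters
  ), p$report)
  p
}
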