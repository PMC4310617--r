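# Shared fixtures: a small synthetic configuration for fast unit tests, a
# random-interval generator, and the brute-force O(nm) overlap oracle that
# the indexed mapping is checked against.

small_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_transcripts = 600,
                   n_samples = c(tissue = 40),
                   chrom_sizes = c(chr1 = 6e7),
                   n_families = 60)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

random_intervals <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                             max_pos = 10000, max_len = 500) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    score = sample(0:1000, n, replace = TRUE),
    label = sample(c("", LETTERS), n, replace = TRUE)
  )
}

# all-pairs reference for map_peaks_to_windows
brute_force_map <- function(windows, peaks) {
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(peaks))) {
      ov <- overlap_length(windows$chrom[i], windows$start[i],
                           windows$end[i], peaks$chrom[j], peaks$start[j],
                           peaks$end[j])
      if (ov > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(tx_id = windows$tx_id[i], peak = j, overlap = ov,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(tx_id = character(), peak = integer(),
                      overlap = integer()))
  do.call(rbind, rows)
}

# per-base membership count, the elementary overlap oracle
per_base_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b,
                             end_b) {
  if (chrom_a != chrom_b) return(0L)
  length(intersect(seq(start_a, end_a - 1), seq(start_b, end_b - 1)))
}
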