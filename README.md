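# promarch

Does promoter architecture predict where a gene is expressed? `promarch` is
an R package for regulatory genomicists who want to relate the
transcription-factor binding-site (Tfbs) content of proximal promoters —
ChIP-seq peaks mapped to a symmetric window around the TSS — to the breadth
of expression measured from CAGE TPM tables, and to ask how that
relationship evolves between paralogs.

## What it computes

* **BoE (breadth of expression)** — the fraction of samples in which a
  transcript is 'on', `BoE = #{s : TPM_s > c} / S` at the cutoff `c = 10`
  TPM (≈ 3 mRNA copies/cell at 300,000 mRNAs/cell), with the breadth classes
  unexpressed / narrow (BoE ≤ 0.33) / intermediate / housekeeping
  (BoE > 0.66) and the broad-vs-rich quadrants A–D (rich: ≥ 10 Tfbs).
* **Tfbs-count metrics** — the four counting variants per promoter window
  (total, unique labels, and both excluding polymerase-class labels), count
  distribution summaries (Tukey five numbers), and per-TF count matrices.
* **Effective promoter size** — a loess-smoothed window sweep whose first
  derivative localizes where TSS-proximal peak enrichment decays into the
  linear background regime.
* **Association machinery** — correlation with t-form statistics, Spearman
  partial correlations by the precision-matrix method, a promoter-shuffle
  permutation null, correlation-distance clustering (1 − r, average
  linkage, Newick export), and a radial-kernel SVM predictor of BoE/PEM
  (cost = 1, γ = 0.01, ε = 0.1) with scrambled and retained controls.
* **PEM (preferential expression measure)** — `tpm_s / mean(tpm)` per
  sample, and its per-sample average over transcripts.
* **Paralog divergence** — the Jaccard index `JI = |X ∩ Y| / |X ∪ Y|` of
  two promoters' TF repertoires against paralog co-expression, all-pairs or
  youngest-pair comparisons, duplication-age stratification
  (Primate < Mammalian < Vertebrate < Animal < Eukaryotic) with Wilcoxon +
  Holm tests, and the event classes housekeeping-conserved /
  tissue-sp.-conserved / transformative.
* **Stacking test** — pooled pairwise overlap percentages of peaks within
  each promoter against a within-window positional randomization.
* **Synthetic data** — seeded generators (`synthetic_config()`,
  `simulate_dataset()`) that plant a heavy-tailed count law, a 3,000 bp
  enrichment scale, TSS stacking, a monotone richness→breadth link, and
  age-decaying paralog JI/co-expression, so the whole pipeline is testable
  without consortium downloads.

File formats: BED6 for peaks/annotations, tab-delimited OSC-style TPM
tables, tab-delimited paralog-pair tables (duplicator columns), JSON/YAML
run configs. `run_stage()` orchestrates the stages
(`simulate`, `profile`, `breadth`, `associate`, `boundary`, `stacking`,
`paralogs`, `predict`) on files, with a manifest beside every output;
`inst/scripts/promarch.R` is a thin command-line wrapper over it.

## Worked example

```r
library(promarch)

# simulate a study: annotations, ChIP-seq-like peaks, TPM expression
cfg <- synthetic_config(seed = 42, n_transcripts = 2000)
ds <- simulate_dataset(cfg)

# map high-quality peaks onto +/-500 bp promoter windows
peaks <- filter_by_score(ds$peaks, 500)
windows <- promoter_windows(ds$annotations, half_width = 500)
mapping <- map_peaks_to_windows(windows, peaks)
profile <- count_metrics(mapping, tx_ids = ds$annotations$tx_id)

# per-transcript breadth of expression at the 10 TPM cutoff
boe <- breadth(ds$expression$values, cutoff_tpm = 10)

# the headline association, with its permutation null
print(correlate(profile$tfbs_total, boe))
null <- shuffle_null(profile$tfbs_total, boe, n_reps = 1000, seed = 1)
cat(sprintf("permutation null: mean t = %.4f, empirical p = %.4g\n",
            mean(null$replicates), null$empirical_p))

# effective promoter size from the window sweep
be <- estimate_boundary(ds$annotations, ds$peaks)
cat(sprintf("estimated promoter boundary: %d bp from the TSS\n", be$boundary))

# paralog promoter divergence vs co-expression
rec <- divergence_records(ds$paralogs$pairs, ds$paralogs$repertoires,
                          ds$paralogs$expression)
print(divergence_analysis(rec))
```

Output:

```
pearson correlation: r = 0.4530, stat = 22.7143, df = 1998, p = 8.608e-102, n = 2000
permutation null: mean t = -0.0146, empirical p = 0.000999
estimated promoter boundary: 3000 bp from the TSS
pearson correlation: r = 0.7023, stat = 46.8594, df = 2256, p = 0, n = 2258
```

Reading it: transcripts with more binding sites in their ±500 bp promoter
are expressed in more tissues (r = 0.45 against the planted coupling of that
strength; the shuffle null is centered at 0 and the observed statistic beats
all 1,000 permutations, so the empirical p is at its 1/1001 floor). The
window sweep recovers the planted 3,000 bp enrichment scale as the promoter
boundary. Between paralogs, promoter repertoire similarity (JI) and
co-expression are strongly coupled (r = 0.70 over 2,258 pairs) — both decay
with duplication age, as planted.

See `vignettes/promoter-architecture.Rmd` for the models, parameter
conventions, generator calibration, numerical choices, and known
limitations (including an honest analysis of the SVM scrambled control's
positive bias).

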