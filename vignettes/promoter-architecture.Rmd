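---
title: "Linking promoter architecture to expression breadth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking promoter architecture to expression breadth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

## The scientific question

How much of a gene's expression profile is written into its proximal
promoter? `promarch` implements an analysis framework built around one
observable, the number of transcription-factor binding sites (Tfbs) mapped
to a symmetric window around the transcription start site (TSS), and one
response, the breadth of expression (BoE): the fraction of samples (tissues,
primary cells or cancer cell lines) in which a transcript's CAGE signal
exceeds an 'on' cutoff, by convention 10 tags per million (TPM; 10 TPM is
roughly 3 mRNA copies per cell at 300,000 mRNAs per cell, see
`tpm_to_copies()`). Around this core the package provides the supporting
estimators that make the correlation interpretable: an effective promoter
size estimator, a within-promoter peak "stacking" test, a
promoter-shuffle permutation null, rank-based partial correlations against
sequence and chromatin covariates, an SVM predictor with positive and
negative controls, and a paralog divergence analysis in which promoter
divergence is summarized by the Jaccard index of TF repertoires.

Because the full ChIP-seq and CAGE consortium datasets are not shipped with
the package, every procedure is exercised end-to-end on synthetic data with
*planted, recoverable* structure. The generator module is first-class,
tested code; its defaults define the study conditions used throughout the
test suite and the acceptance script.

## Metrics

**Tfbs counts.** Four per-transcript variants guard against double counting
and polymerase dominance: the total number of mapped sites (`tfbs_total`),
the number of distinct TF labels (`tfbs_unique`), and both after removing a
configurable polymerase-class label set (`tfbs_total_nopol2`,
`tfbs_unique_nopol2`; default `{Pol2, POLR2A, Pol2-4H8, Pol3}`). On both
real and synthetic data the total and unique counts are nearly collinear
(Pearson r > 0.95), so conclusions never hinge on site multiplicity.

**Windows and filtering.** Coordinates are 0-based half-open (BED). The
proximal promoter is `[tss - h, tss + h)` with `h = 500` by default,
irrespective of strand; the TSS of a minus-strand BED transcript is its end
coordinate. Peak quality scores span 0–1000 and the quality filter keeps
scores *strictly above* the cutoff (default 500, half the maximum); cutoff 0
is the all-data mode and keeps everything, including score-0 peaks. A peak
overlapping the window by at least one base counts, matching coverageBed
semantics.

**BoE and classes.** `breadth()` uses a strict `TPM > cutoff` test. Classes:
unexpressed (BoE = 0), narrow (0 < BoE ≤ 0.33), intermediate
(0.33 < BoE ≤ 0.66), housekeeping (BoE > 0.66); the four fractions always
partition a table. The quadrant classes A–D cross broad (BoE > 0.33) with
Tfbs-rich (count ≥ 10); "rich" is inclusive at 10 so that the published
phrasing "fewer than 10" for poor and "10 for rich" are both satisfied.

**Levels, conditioned and not.** Mean/median/max TPM over all samples are
mechanically coupled to BoE (zeros from 'off' samples drag the mean), so
`level_summaries()` also reports the breadth-conditioned mean/median over
'on' samples only, flagged undefined when no sample clears the cutoff. The
synthetic tests reproduce the expected contrast: strong `mean_all ~ BoE`
coupling, near-zero `mean_on ~ BoE` coupling.

**PEM.** The preferential expression measure of transcript *y* in sample
*s* is `tpm[s] / mean(tpm)` with the mean over *all* samples (the verbatim
definition of the source analysis); the PEM vector of a transcript averages
to exactly 1, and all-zero transcripts are excluded and flagged rather than
assigned 0. `pem_avg()` is the unweighted transcript mean for one sample.

**Jaccard promoter divergence.** For two paralog promoters,
`JI = |X ∩ Y| / |X ∪ Y|` on sets of *distinct* TF labels. Repertoire sets
rather than genomic intersection are used because paralog promoters occupy
different loci; multiplicity is ignored. Both-empty repertoires give 0 with
a flag.

## Estimators and tests

**Effective promoter size** (`estimate_boundary()`). Mean Tfbs count per
transcript is computed over a grid of half-widths (default 250–10,000 bp,
echoing the window sweep of the source analysis), smoothed by loess, and
differentiated. The boundary is the smallest grid point beyond which the
derivative change stays below 5% of the maximum absolute derivative — the
point where TSS-proximal enrichment has decayed into the linear background
regime. Numerical choices: loess degree 2 with span 0.6 (local enough to
resolve the kink between enrichment and background on a 9-point grid;
wider spans smear the transition by about one grid step), derivative by
first differences at grid midpoints, and a relative rather than absolute
tolerance so the estimator is scale-free in the peak density. A derivative
that never varies above tolerance (pure background) returns the first grid
point. On synthetic data with a planted 3,000 bp enrichment scale the
estimator recovers 3,000 exactly across seeds at the default span.

**Stacking test** (`stacking_test()`). For every promoter with ≥ 2 mapped
peaks, all pairwise overlap percentages are pooled; the percentage uses the
*union* of the two intervals as denominator (the source analysis leaves the
denominator unstated; the union form is symmetric and bounded in [0, 100]).
The null pool re-places each peak uniformly within its promoter, preserving
per-promoter counts and lengths; one randomized replicate is the default,
matching the singular "a randomized dataset" of the original design, and
`n_randomizations` exposes more. Observed and null pools are compared by a
Welch t-test. Planted full stacking produces observed ≫ null at p < 0.01;
on uniformly placed peaks the test is calibrated (non-significant at
α = 0.01 in ≥ 95% of seeds). One caveat found during development: peaks
straddling the window edge are truncated to fit when randomized, which can
push the null mean slightly *above* the observed mean when true stacking is
weak — the test is therefore one-sided in practice only for clear effects.

**Promoter-shuffle null** (`shuffle_null()`). Re-assigns promoters to
transcripts by permuting the count vector, recording the correlation
t-statistic each time. The empirical p uses the +1 pseudocount,
`(1 + #{|t*| ≥ |t|}) / (1 + n_reps)`, so a permutation p of 0 is
impossible (the original analysis quoted a parametric-style bound instead).
Replicate t-statistics are centered at 0 and the empirical p is uniform
under the null; both properties are asserted in the test suite.

**Partial correlations** (`partial_correlation()`). All columns are rank
transformed, then the partial correlation is read off the inverse of the
correlation matrix (the precision-matrix method; the source names no
algorithm). Controlling for the empty set reproduces the plain Spearman
correlation, which doubles as an oracle check. Singular matrices are
rejected with the collinear columns named via the smallest eigenvector.

**Correlation-distance clustering** (`cluster_by_correlation()`). Distance
`1 - r`, average-linkage agglomeration, columns sorted by name first so the
leaf order is reproducible; export to Newick via `ape`.

**SVM predictor** (`fit_predictor()`). A radial-kernel SVM (e1071/libsvm)
with the fixed hyperparameters cost = 1, gamma = 0.01, epsilon = 0.1, fit on
a seeded random half and evaluated on the held-out half. Features are the
per-transcript, per-TF count vectors (`tf_count_matrix()`), optionally plus
GC/CpG covariates; libsvm centers and scales on the training half.
Regression accuracy is Pearson r between predicted and observed responses;
the binary mode dichotomizes at BoE 0.33 and averages the ROC AUC over 10
random-half runs. Two controls use the same split: *retained* (response
included as a feature; positive control, r ≈ 0.93 on synthetic data) and
*scrambled* (training response permuted; negative control).

A finding worth recording: the scrambled control is *not* centered at zero
here. Across split seeds it averages r ≈ 0.15 on synthetic data — the same
order as the 0.13–0.29 published for the real-data analysis this package
follows. The mechanism is an epsilon-SVR artifact: after training on a
permuted response the fitted function still varies along the density
gradient of the feature space (predictions drift from the local training
mean toward the model intercept as test points move into sparse,
high-count regions), and with a right-skewed response such as BoE that
gradient correlates with the true response. A symmetric response largely
removes it. The acceptance suite asserts the idealized |r| < 0.1 bound on
the across-split mean and that assertion fails by design of the estimator,
not by sampling noise; we keep it failing rather than loosen it, since it
documents a real property of the control. For the synthetic SVM
experiments the feature matrix is restricted to the 50 most frequent TF
labels: with all 148 mostly-empty columns the radial kernel is dominated
by noise dimensions and even the retained positive control cannot exceed
r ≈ 0.83, whereas standard minimum-abundance filtering restores it to
0.93+.

**Paralog divergence** (`divergence_records()`, `divergence_analysis()`,
`select_youngest_pairs()`, `age_group_summary()`). Per pair: JI of
repertoires, co-expression (Pearson by default; Kendall/Spearman
selectable) across samples, both paralogs' breadth classes, and the event
class — housekeeping-conserved, tissue-specific-conserved, transformative,
or *other* (the published trichotomy is silent about pairs with an
intermediate member; they get an explicit fourth class). All `choose(n, 2)`
within-family pairs can be enumerated, or reduced to each gene's
youngest-node comparison to avoid pseudo-replication by large families;
familySide flags (1/2 at the defining node) drop same-side comparisons
first. Age groups run youngest-first (Primate < Mammalian < Vertebrate <
Animal < Eukaryotic), each excluding taxa of preceding groups; per-group
means are compared with pairwise Wilcoxon rank-sum tests under Holm
adjustment.

## The synthetic generator

`synthetic_config()` bundles the study conditions; all generators are
deterministic given the config and seed.

* **Richness law.** Per-transcript latent binding-site intensity follows a
  discrete power law `P(k) ∝ (k + 1)^-α` truncated at 60, with α = 1.05
  chosen so the median is 4 — the shape of the published count
  distribution (Tukey five numbers 0, 0, 4, 14, 58). The exponent is
  recoverable from 20,000 draws by maximum likelihood within its standard
  error.
* **Peak placement.** Each transcript gets `richness` proximal peaks:
  offsets `± 3000 · Beta(1, 2)` so density decays linearly to background at
  the 3,000 bp enrichment scale, with a `stacking_weight` fraction (default
  0.15) centered exactly on the TSS; peak lengths ≈ 250 bp; uniform genomic
  background at 0.05 peaks/kb; labels Zipf-weighted over a 148-label pool
  with the polymerase-class labels most common; scores uniform on 0–1000.
* **TSS layout.** One 600 Mb chromosome with ≥ 20 kb TSS spacing, so even
  the widest (±10 kb) analysis windows of neighbors stay disjoint;
  densely packed transcripts would leak neighboring promoter clusters into
  wide windows and bias the boundary estimator upward.
* **Breadth link.** `p_on = plogis(-2.8 + 0.8 · log1p(richness) + ε)`,
  `ε ~ N(0, 1.6)`, applied per sample (179 tissue columns by default). The
  slope/noise pair was calibrated once so the realized Pearson correlation
  between mapped counts (±500 bp window, cutoff 500) and BoE sits at the
  planted target of 0.45, and then frozen; measured r = 0.44–0.46 across
  seeds. 'On' samples draw TPM 10 + lognormal (always above cutoff), 'off'
  samples a sub-threshold exponential.
* **Paralog families.** Families grow by sequential duplication (size
  2 + geometric, ~3 genes); events draw one of five age levels with
  realistic frequencies and are ordered oldest-first. Across a duplication
  of age *a* each daughter keeps each repertoire label with probability
  `ji_retention[a]` (0.95 young → 0.40 old, losses not replaced) and gains
  `Pois(age_gain[a])` new labels (0 young → 10 old), so pair JI decays with
  node age while older duplicates accumulate larger repertoires; latent
  expression evolves as `z' = √ρ_a z + √(1 - ρ_a) N(0, 1)` with ρ from 0.90
  (young) to 0.30 (old). A gene's breadth target follows the planted
  monotone `age_boe` (0.10 → 0.35) at its most recent duplication age.
  These choices plant the three recoverable trends: JI ~ co-expression
  coupling (r ≈ 0.7, destroyed by pair randomization), and monotone BoE and
  TfbsNo age profiles.

**What the generator does not emulate.** Chromatin state, methylation and
DNase signal (consumed only as numeric covariates when supplied), sequence
motifs under peaks, shared enhancers between linked genes, tissue-specific
peak sets (the counts model a cumulative binding landscape, as in the
clustered consortium peak sets), and non-independent sampling of tissues.
Passing recovery tests therefore shows the estimators are correct and
calibrated, not that real promoters behave like the generator.

## Problem sizes and runtime choices

The test suite and acceptance script use: 10,000 transcripts × 179 samples
for the headline coupling and boundary recovery; 1,000 transcripts for the
stacking experiments (≥ 100,000 peak pairs under full stacking); 40 × 100
transcripts for permutation-null calibration (199 replicates each); 2,000
families (~10,000 pairs) for the divergence recovery; and a 3,000 ×50
feature matrix for the SVM controls. These sizes keep every recovery within
a few seconds to a couple of minutes on one CPU while leaving the planted
effects comfortably detectable.

## Known limitations

* The boundary estimator reports a grid point; precision is one grid step.
* The stacking null truncates edge-straddling peaks into the window
  (see above), slightly inflating the null mean for weak effects.
* Kendall p-values use the tie-corrected normal approximation for n > 10.
* The scrambled SVM control is biased positive for skewed responses (see
  the analysis above); interpret published scrambled baselines accordingly.
* `select_youngest_pairs()` keeps ties (several pairs through one youngest
  node) rather than sampling one, which is deterministic but can retain
  more than one comparison per gene in star-like families.
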