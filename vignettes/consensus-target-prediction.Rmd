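---
title: "Predicting miRNA targets from pan-cancer correlation consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA targets from pan-cancer correlation consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpancor)
```

## The problem and the model

MicroRNAs (miRNAs) regulate gene expression post-transcriptionally, most
often by repressing target mRNAs, occasionally by activating them. Curated
interaction databases cover only a fraction of genuine miRNA-gene
relationships, so the pairs *absent* from databases mix true negatives with
undiscovered targets. `mirpancor` treats target discovery as a
positive-unlabeled classification problem over miRNA-gene pairs:

1. **Features.** For each pair $(m, g)$ and each disease cohort $c$ the
   feature is the Pearson correlation $r_{mg}^{(c)}$ between the miRNA's and
   the gene's log expression, computed over the samples in which *both* are
   expressed (value $> 0$). A pair is described by its vector of per-cohort
   correlations; cohorts where the correlation cannot be computed contribute
   missing values.
2. **Labels.** A pair is positive iff it appears in the union of the
   *training* interaction databases; all other retained pairs are negative.
   Databases designated for validation are refused at labeling time, by
   construction of `assign_labels()`, so no held-out knowledge can leak into
   training.
3. **Ensemble.** Because positives are rare (on the order of 0.1%), a single
   classifier fit is dominated by the negative class. Instead, at each
   downsampling rate $\rho$ the negative class is subsampled without
   replacement to $\rho \cdot n_{neg}$, combined with all positives, split
   80/20 stratified by class, and a gradient-boosted tree classifier
   (xgboost, which handles missing feature values natively) is fitted. This
   is repeated for many independent downsamples; every model then scores
   every negative-labeled pair, and a pair called positive (score
   $\ge$ 0.5) by at least a frequency threshold of models is **significant**
   — a consensus vote that is far more stable than any single fit.
4. **Validation.** Significant pairs are checked against held-out databases
   (counting only knowledge absent from the training databases), against
   differential expression after miRNA perturbation (two-sample t-tests,
   DEG iff $p < \alpha$ with no multiplicity correction, deliberately),
   and for concordance between the sign of the pan-cancer correlation and
   the direction of regulation under perturbation: under overexpression an
   up-regulated DEG should correlate positively, a down-regulated one
   negatively; under knockdown the rule is mirrored.

## Filtering rules and their exact semantics

Two filters are strict by design and tested as such:

* a cohort's correlation is computed only when the number of co-expressing
  samples **exceeds** `min_coexpressing` (default 10) — exactly 10
  co-expressing samples yields MISSING, 11 yields a value;
* a pair is retained only when it is MISSING in **at most** `max_missing`
  cohorts (default 3) — missing in 4 cohorts excludes the pair.

Whether the correlation itself should use only the co-expressing subset or
all samples (with the count acting as a gate) is genuinely open; both are
implemented (`use_all_samples`), and the subset-only variant is the default
because the co-expressing samples are the observations on which both
features are measured. Missing correlations are carried as native `NA`
into the learner rather than imputed, since gradient-boosted trees route
missing values through learned default directions; zero-imputation would
silently conflate "unknown" with "uncorrelated".

## The synthetic generator: what it emulates and what it does not

`simulate_panels()` emulates the three inputs the real analysis consumes,
with planted ground truth so that every downstream stage is testable:

* multi-cohort log-scale expression with zeros denoting non-expression.
  miRNA marginals are truncated Gaussians (mean 4, sd 1.5 log units);
  genes are per-gene baselines plus Gaussian noise. For a planted pair
  active in a cohort the gene receives `sign * beta * (m - mean(m))`;
  centring the miRNA keeps the gene near its baseline so that the planted
  co-variation is not distorted by clipping at zero. Dropout then zeroes
  entries independently (default probability 0.1), exercising the
  co-expression filter.
* interaction knowledge split into three disjoint planted tiers:
  `training` (labels), `heldout` (validation databases), `undiscovered`
  (true effects no database knows) — the tier structure that makes a
  "validation rate" meaningful.
* two-group perturbation experiments in which planted targets of the
  perturbed miRNA shift by `sign * shift` under overexpression.

Defaults are desk-scale study conditions chosen once: 8 cohorts, 60 miRNAs
x 300 genes (18,000 pairs — enough to make the class imbalance real), 120
samples per cohort, 500 planted pairs (300/100/100 across tiers), effect
sizes 0.5-1.5 log units against noise sd 0.5. The generator does **not**
model batch structure, cohort-specific expression programs, count noise,
or sequence information; passing tests therefore demonstrate the
pipeline's logic and its statistical calibration, not performance on real
tumor data, where signal-to-noise is far lower and confounding abounds.

## Numerical choices

* The full pair x cohort correlation table is computed in closed form from
  crossproducts against the co-expression indicator matrices (values
  outside a feature's support are exactly zero, so subset sums reduce to
  crossprods); a brute-force per-pair recomputation is the test oracle.
  Sub-vectors whose variance is zero up to float tolerance are set MISSING,
  and results are clamped to $[-1, 1]$.
* Per-model seeds derive from `base_seed` at fixed offsets, and xgboost
  runs single-threaded, so identical configurations reproduce identical
  consensus counts; pipeline stage seeds derive from the global seed at
  fixed offsets recorded in the run manifest.
* The classifier-score cutoff for a "positive call" is 0.5; the learner
  uses library defaults (depth 4, eta 0.3, 30 rounds) with no tuning.
* The t-test defaults to the Welch form; identical paired vectors in
  `paired_overlap_ttest()` return $t = 0, p = 1$ as the natural limit.
* Percentages follow reporting conventions: validation rates to two
  decimals, DEG-overlap and concordance percentages to the nearest integer.
* Tie-breaks in `select_matched_predictions()` are lexicographic on gene
  id, making size-matched comparisons deterministic.

## Reference scale used by the checks

The acceptance-style checks and `scripts/acceptance.R` run the pipeline at
the generator defaults above with 20 models per rate over rates
{0.01, 0.05, 0.1, 0.5, 1.0}, reporting significant pairs at rate 0.1 with
a 70% frequency threshold. At this scale the suite reproduces the
qualitative behaviour expected of the method: recall decreases and
specificity increases along the downsampling grid, significant sets nest
across frequency thresholds, shuffled labels give chance AUC, null
perturbations call DEGs at the nominal rate, and consensus calls are
enriched for held-out planted pairs by well over an order of magnitude
above their background prevalence among negatives.

## Known limitations

* Negatives are contaminated with undiscovered positives by construction;
  the consensus frequency mitigates but cannot remove this.
* Correlation features capture only monotone linear co-variation within
  cohorts; regulation that manifests non-linearly or only in unprofiled
  contexts is invisible.
* The concordance check uses the correlation sign from a single matched
  cohort; entries whose matched-cohort correlation is MISSING are skipped
  rather than imputed.
* External tool predictions (sequence-based methods) are accepted as
  scored tables for size-matched comparison; running those tools is out of
  scope.
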