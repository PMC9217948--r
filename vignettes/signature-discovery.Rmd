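---
title: "Stochastic discovery of prognostic transcriptomic signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic discovery of prognostic transcriptomic signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Biochemical recurrence (BCR) after prostatectomy is the first sign of
prostate-cancer relapse, and stratifying Gleason-score >= 7 patients by
relapse risk from prostatectomy expression profiles is a long-standing goal.
Signatures mined directly from the top outcome-associated genes of one
cohort tend to overfit that cohort.  `prognosig` implements an alternative
strategy: start from a biologically informed candidate pool — genes whose
expression associates with a progression-relevant mutation status (TP53 in
the motivating application) — and search that pool stochastically, letting a
gene's selection be driven by the post-hoc performance of many random
signatures that contain it rather than by its single-gene outcome ranking.

# The discovery procedure

Given an expression matrix (genes x samples, log2 scale), a binary BCR
label per sample, and a candidate pool:

1. **Random signatures.** `n_subsets` subsets of `subset_size` genes
   (default 1000 subsets of 25) are sampled uniformly without replacement
   from the pool.  Subsets are drawn independently; duplicates are not
   deduplicated.
2. **Scoring.** Each subset is scored by SVM leave-one-out
   cross-validation (`svm_loocv()`): for every sample $i$, a
   C-classification SVM (linear kernel, cost 1, default gamma, class
   weights equal to the reciprocal of the training-fold class ratio) is
   trained on the other $N-1$ samples and produces a decision value $t_i$,
   oriented so positive means the relapse class; $\hat z_i =
   \mathrm{sign}(t_i)$ with $\mathrm{sign}(0) \mapsto +1$.  The subset's
   AUC is the Mann–Whitney concordance between labels and $t$, and its
   association p-value is the two-sided Fisher exact test of the true
   versus predicted 2x2 table.
3. **Filter.** Subsets with AUC $\ge$ 0.65 **and** $p \le 10^{-4}$ (both
   inclusive) are selected; genes appearing in at least `min_hits`
   (default 3) selected subsets form the *initial* signature.
4. **Wrapper.** For each initial gene $g_i$, $A_{(-i)}$ is the LOOCV AUC
   without $g_i$; the genes are re-ordered for backward elimination so
   that the most expendable genes — those whose removal yields the
   *highest* AUC — are dropped first.  $B_{(-1:i)}$ is the LOOCV AUC of
   the suffix $\{g^*_{i+1},\dots,g^*_m\}$, with gene count $C_i = m - i$,
   down to the size floor `k_min` (default 10); it typically rises while
   eroding or redundant genes are shed and falls once the signal core is
   reached.  A smoothing spline of $B$ on $C$ is fitted, its mode $c^*$
   located by a 1000-point grid search over the observed $C$ range, and
   the observed point with the largest $C$ strictly below $c^*$ is chosen;
   its suffix is the final signature.

   With `spline_df = "auto"` the smoothing starts from the effective df
   chosen by generalized cross-validation and is then reduced stepwise
   until the fitted curve is unimodal over the evaluation grid: the
   stopping rule presupposes a *single-mode* curve, and on long, noisy
   suffix-AUC traces plain GCV returns a high-df, multi-modal wiggle whose
   argmax is an arbitrary local bump.  Enforcing unimodality makes the
   "mode" a well-defined object before the adjacent-left rule is applied.

   The elimination direction deserves a note: the backward-elimination
   role of the wrapper — removing the genes that erode the prediction
   strength of the reduced signature — requires dropping high-$A_{(-i)}$
   genes first.  Ordering the drop sequence the other way (lowest
   $A_{(-i)}$ first) removes the most valuable genes immediately, makes
   $B$ monotone in $C$ so the spline mode sits at the right edge, and
   reduces the procedure to "always keep $m-2$ genes" while retaining
   exactly the eroding genes it is meant to remove.

The published procedure pinpoints the point left of the spline mode
*visually*; reproducibility demands a deterministic rule, so the grid-search
automation above is used, with two degenerate-case rules: a flat curve
falls back to the smallest observed $C$ (parsimony), and a failed spline
fit falls back to the maximal observed $B$ (with a warning).  Smoothing is
chosen by generalized cross-validation by default (`spline_df = "auto"`).

The choice of two-sided Fisher p for filtering random subsets and one-sided
for reporting a final signature follows the published evaluation protocol.

# Evaluation protocol

* **Cross-cohort validation** (`evaluate_cross_cohort()`): one model
  trained on the full discovery cohort, applied to an external cohort;
  AUC/Fisher p computed there.  Cohorts measured on different platforms are
  first reconciled by `homogenize_q75()`, which rescales the second matrix
  so both share one global 75th percentile (see *Numerical choices*).
* **Robustness** (`robustness_analysis()`): `n_reps` working sets of
  `floor(frac * N)` samples (defaults 500 and 0.9) are drawn without
  replacement; signature rows are z-scored on the working set and perturbed
  with $\mathcal N(0, \sigma^2 = 0.1)$ noise — i.e. noise worth 10% of the
  unit data variance — before LOOCV.  The report keeps the full AUC vector,
  its 0.05/0.95 quantiles, and the fraction below 0.65.
* **Survival utility** (`km_logrank()`, `compare_models()`): predicted BCR
  groups stratify relapse-free survival (Kaplan–Meier curves, two-group
  log-rank).  Three Cox proportional-hazards models are compared: M-1 with
  the continuous LOOCV decision value (transcriptomic risk score, TRS) as
  the only covariate, M-2 with the clinicopathologic factors (Gleason
  category 3+4 / 4+3 / other, T stage T1/T2/T3, age), M-3 with both.  Each
  model reports Royston's $D$-based explained variation
  $R^2 = \frac{D^2/\kappa^2}{D^2/\kappa^2 + \pi^2/6}$, $\kappa^2 = 8/\pi$
  (the prognostic index is replaced by Blom normal order scores scaled by
  $1/\kappa$, and $D$ is the Cox coefficient of that covariate), the
  score-test p-value, and $\mathrm{BIC} = -2\,\ell + q \ln D_{events}$.
  Using the event count as BIC's effective sample size follows the
  Volinsky–Raftery convention for partial likelihood; tie handling is
  Breslow throughout (simulated times are continuous, so ties are rare).

# The synthetic-cohort generator

Real multi-cohort data cannot ship with the package, so every stage is
exercised against `simulate_study()`, which emulates the statistical
structure the method assumes:

* background log2 expression of gene $g$ is
  $\mathcal N(\mu_g, \sigma_g^2)$ with $\mu_g \sim \mathcal N(7, 2^2)$,
  $\sigma_g \sim \mathcal U(0.5, 1.5)$ — plausible log2-scale
  heterogeneity;
* a binary mutation covariate ($\Pr = 0.3$, about the TP53 rate in
  GS >= 7 prostate tumors) shifts `n_mut_assoc` planted genes by
  `deg_effect` $\cdot\ \sigma_g$ (default 0.5 SD);
* the latent risk sums `prog_effect` (default 0.5) times the
  *standardized residual* expression of the `n_prognostic` planted
  prognostic genes, a direct mutation hazard term (`mut_effect`, default
  0.7, hazard ratio about 2), and independent clinicopathologic terms;
* relapse times are exponential with hazard
  `baseline_hazard` $\cdot\, e^{r - \bar r}$ (defaults 0.05/yr, censored
  administratively at 10 yr, giving roughly 30–45% events, inside the range
  of published GS >= 7 cohorts); the binary BCR label is $+1$ exactly when
  the event precedes censoring, so label and event indicator always agree;
* cohort 0 is the discovery cohort; later cohorts get per-gene
  batch effects (log-normal scale, SD 0.1; additive shift, SD 0.5)
  emulating platform differences, plus a share of "unexpressed" genes
  (exact zeros in 70% of samples for 5% of background genes) so the
  expression filter has something to remove.

Two design points deserve emphasis.  First, the risk must ride on the
*residual* expression rather than the raw z-scores: the mutation shift is
common to all planted genes, so raw z-scores would stack `n_prognostic`
coherent copies of it into the log-hazard and mutation status alone would
determine every outcome.  Even as noise the shift matters — its direction
in feature space is exactly the signature direction, so large `deg_effect`
values cap the AUC any classifier can reach; the defaults keep that
ceiling above 0.85 while the explicit `mut_effect` term preserves the
biologically expected mutation–outcome association.  Second, BCR labels
and relapse events are deliberately coupled (no separate label noise), the
binary-endpoint convention of the motivating analysis.

Determinism: gene-level truth (means, SDs, planted identities) is drawn
from the master seed; each cohort's sample-level stream is seeded with
`seed + cohort_index + 1`, so cohort 0 never replays the truth stream and
any cohort can be regenerated standalone.

What the generator does **not** emulate: negative-binomial count noise,
library-size variation, gene–gene correlation blocks, informative
censoring, or missing clinical covariates.  Passing recovery tests on this
generator therefore shows the pipeline's statistical machinery is sound,
not that any particular real cohort will yield a 25-gene signature.

# Numerical choices

* Quantiles are type-7 (linear interpolation) everywhere (IQR, q75).
* `quantile_normalize()` delegates to `limma::normalizeQuantiles(ties =
  TRUE)`; probe-IQR ties in `collapse_by_iqr()` break to the
  lexicographically smallest feature id.
* The q75 homogenization is multiplicative on the stored log2 scale; the
  alternative (additive shift) is indistinguishable for rank-based
  downstream metrics with a linear kernel, and the multiplicative form
  preserves the zero point of unexpressed genes.
* SVM features enter on the stored log2 scale without per-fold
  standardization (`scale = FALSE`); z-scoring appears only in the
  robustness analysis, as a dataset alteration applied before
  cross-validation (full working set, not per fold).
* LOOCV uses an exact shortcut: folds leaving out the same class share
  identical training-fold class weights, so one full-data model per class
  is fitted and only its support vectors are refitted per fold (removing a
  non-support-vector cannot change a soft-margin SVM solution).  The
  shortcut is verified against a naive per-fold loop in the tests.
* Decision-value orientation is normalized internally (positive means
  class +1) because the backend's sign convention depends on label order
  in the training data.
* Welch's unequal-variance t-test is used for the DEG scan (the default
  two-sample t in this environment); genes with zero variance in both
  groups get $p = 1$ (equal means) or $p = 0$ (unequal) by convention.
* "Unexpressed" means exactly 0 on the stored scale, matching TPM data
  under the log2(x + 1) transform.

# Problem sizes used in the shipped checks

The package's own test suite and the `scripts/acceptance.R` report run
entirely on simulated cohorts.  The end-to-end recovery check uses a
2-cohort study with n = 250 samples, 2000 genes, a 120-gene planted
candidate pool with 15 prognostic genes at `prog_effect = 1.0` (the strong
scenario), discovery with 300 subsets of 15 genes and `k_min = 8`, followed
by homogenized cross-cohort validation; DEG recovery uses 2000 genes with
100 planted at 1 SD and n = 200; survival calibration uses n = 500 null
and graded-effect simulations and 200 null replicates for the log-rank
uniformity check; robustness summaries use 60–100 working sets.  These sizes
keep the whole suite comfortably reproducible on a laptop while leaving
every statistical conclusion stable under reasonable seed changes.

# Known limitations

* The wrapper's spline rule assumes a single-mode suffix-AUC curve; on
  multimodal or flat curves it falls back to deterministic parsimony
  rules rather than judgment.
* Fisher p-values on LOOCV label tables ignore the dependence between
  folds; they are comparative scores here, not calibrated error rates.
* `homogenize_q75()` corrects only a global scale difference between
  cohorts; per-gene batch effects require upstream normalization.
* The tuned-hyperparameter path (`cost`, `gamma` via `svm_settings()`) is
  exposed but never auto-tuned; honest use requires an independent test
  cohort, as in the motivating study's paired-cohort analysis.
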