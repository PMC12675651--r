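---
title: "Methods: sepsis phenotyping, trajectories, proteome screening and compact classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sepsis phenotyping, trajectories, proteome screening and compact classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the parameters that matter, the design choices made
where several defensible options existed, and what the synthetic-cohort
tests do and do not demonstrate about real data.

## 1. The phenotyping model

The core object is a *frozen* fitted model: day-1 standardization
parameters, PCA loadings and k-means centroids packaged together
(`derive_phenotypes()` returns it; `predict()` applies it to any later
day). Freezing is the point — later assessment days are deliberately
transformed with day-1 means and standard deviations and projected onto
day-1 loadings, so that a patient's movement between phenotypes reflects a
change in the patient, never a change in the coordinate system.

Pipeline, in order:

1. **Variable selection.** A variable is retained when its day-1 missing
   fraction is strictly below 0.30 and it is not an excluded treatment
   surrogate (e.g. vasopressor dose — dosing reflects the care team, not
   the organ damage being phenotyped). The denominator is the number of
   patients with any day-1 observation; the published filter gives no
   denominator, so this is our definition and it is stated here once.
2. **Daily aggregation.** Repeated same-day measurements are reduced by
   the clinically informative extreme per variable (maximum for
   creatinine or transaminases, minimum for the quick value or mean
   arterial pressure, median where no direction is privileged). The rules
   live in the packaged catalogue (`clinical_variables()`).
3. **Imputation.** A missing day-1 cell is filled from the same patient's
   value on the nearer of the two subsequent assessment days, then from
   the day-1 cohort median. Lookahead uses *aggregated* daily values: the
   aggregate is the day's summary measurement, and imputing from raw
   repeats would mix aggregation rules.
4. **Standardization.** z-scores with the *sample* standard deviation
   (n − 1). The convention is arbitrary but must be fixed for bit-stable
   z-scores; every frozen parameter inherits it.
5. **Infection focus.** Encoded as one-hot indicators appended *after*
   z-scoring, not z-scored themselves: a 0/1 indicator already lives on a
   bounded scale, and z-scoring rare categories would hand them extreme
   leverage. Age is numeric and is z-scored with the other variables.
6. **PCA.** Components are retained while the cumulative explained
   variance ratio is ≤ the target (default 0.70); the retained count m is
   the smallest with ratio strictly above it. The strict inequality
   matters only on exact ties, where we retain the extra component.
7. **Cluster number.** k-means is fitted for k = 2..8 and the k with the
   largest mean silhouette width (Euclidean distances on the component
   scores) is selected. Candidates yielding an empty cluster are marked
   invalid and excluded from the argmax.
8. **k-means.** `stats::kmeans` (Hartigan–Wong) with 10 random restarts
   under a fixed seed, best solution by total within-cluster sum of
   squares. Multi-restart k-means is the field-standard guard against bad
   local optima; determinism comes from the seed, and a small-instance
   test checks the result against an exhaustive-partition oracle.
9. **Labels.** Clusters are lettered by descending size (A largest). Ties
   go to the lower internal cluster index, so the letter map is a
   deterministic function of the labels.

### Numerical choices

* Nearest-centroid assignment computes squared distances by direct
  differences rather than the expanded quadratic form ‖x‖² − 2x·c + ‖c‖²:
  the expansion loses the exactness of ties, which are specified to
  resolve toward the lower cluster index.
* The serialized model (`write_phenotype_model()`) stores every float with
  17 significant digits, the minimum that round-trips IEEE doubles, so a
  reloaded model reproduces projections bit-exactly.
* Zero-variance columns make the z-transform undefined; the standardizer
  fails naming the column rather than silently dropping it, because a
  constant clinical variable in real data almost always signals an
  upstream extraction bug.
* Later-day imputation uses the *day-1* cohort medians as the fallback
  (frozen, like the standardizer), so no information flows backwards from
  later days into the coordinate system.

## 2. Trajectories

`build_trajectories()` merges per-day assignments with recorded outcomes.
Death and discharge are absorbing; a patient with no data on a day and no
recorded outcome is `absent` rather than silently dropped, and empty
source states yield `NA` fractions rather than 0 in
`transition_summary()` — a 0 would claim evidence where there is none. The
default assessment grid is days 1, 4, 7, 10; it is configuration, not a
constant.

## 3. Proteome screen

Intensities are analyzed on the log2 scale (the convention for
DIA-quantified protein matrices, and the scale on which the ANOVA
normality assumption is plausible). Batch correction is per-protein
median-centering within batch, adding back the grand median; it removes
location offsets only, which matches the additive batch model of the
generator, and is exposed as its own function so a different strategy can
be swapped in. Missing intensities are excluded pairwise — no proteome
imputation anywhere.

The screen: proteins with ≥ 5 observations in every phenotype are tested
(the filter runs *before* Benjamini–Hochberg, so the correction universe
is the tested set only); one-way classic ANOVA (not Welch — chosen, and
configurable in the sense that the per-protein inputs are plain vectors);
Tukey HSD with the Tukey–Kramer standard error for unbalanced groups; a
pair is flagged when p_FDR ≤ 0.05 and its pairwise p ≤ 0.05. The ANOVA and
Tukey p-values are computed vectorised across proteins (`pf`, `ptukey`)
and are cross-checked in the tests against `stats::aov` +
`stats::TukeyHSD` per protein, and against a 100,000-permutation
max-studentised-range oracle on a small instance. Degenerate proteins
(identical values everywhere) get p = 1 by convention and are never
flagged.

Baseline tables use Kruskal–Wallis for continuous and chi-square for
categorical variables, with pairwise Mann–Whitney / chi-square tests under
Bonferroni correction (×3). Mann–Whitney as the continuous post-hoc is our
choice; only the omnibus tests are forced by the table's conventions.

## 4. Classifier

* **Correlation pruning** (|r| > 0.7): from each offending pair the member
  with the larger mean absolute correlation to all remaining features is
  dropped (ties: alphabetically later name) — it removes the more
  redundant feature while keeping the post-condition (all pairwise
  |r| ≤ 0.7) checkable.
* **Nested MCCV.** Outer stratified 70/30 train/test splits estimate
  generalization; inner 70/30 splits of the training part rank features.
  Stratification is required for a 7% minority class to appear reliably
  in 30% partitions; a split that still loses a class is re-drawn with a
  message.
* **Rebalancing.** The smallest phenotype is bootstrapped (with
  replacement, original rows kept — up-sampling only) to 60% of the
  largest, in every training set, never in a test set.
* **Imputation.** Per-split training medians fill both partitions; a
  sentinel-poisoning test asserts test rows can never touch the medians.
* **Shapley ranking.** Feature importance is the mean over validation
  samples and classes of |φ|, where φ are Monte-Carlo permutation-sampling
  Shapley values: for each explained sample and random feature ordering, a
  background training row is morphed feature-by-feature into the sample,
  and the prediction increments estimate per-feature contributions. This
  estimator is authored in the package; averaging |φ| over classes is our
  multiclass reduction. Features are ordered by ascending median rank over
  inner iterations (ties: mean rank, then name).
* **Knee point.** The Kneedle difference-curve construction for a concave
  increasing curve, sensitivity 1.0: normalize axes, d = y − x, confirm a
  local maximum of d once d falls below its height minus
  sensitivity × mean x-step. No knee (straight or flat curve) returns the
  full feature count with a warning. The implementation is hand-verified
  on a five-point curve whose knee is derivable on paper.
* **Metrics.** Macro (unweighted) recall — "averaged recall" is ambiguous,
  and macro is the variant that does not let the 53% class swamp the 7%
  class; per-class one-vs-rest AUROC (via `pROC`) and precision. A
  train–test gap above 0.1 in any metric adds an explicit overfitting note
  to the report.
* The base learner is a 500-tree probability random forest (`ranger`) with
  default depth; hyperparameters live in `mccv_config()` and are not
  tuned by the package.

The curve and the final evaluation share seed streams, so evaluating the
full ranked feature set reproduces the curve's endpoint exactly — a cheap
invariant that catches split-bookkeeping bugs.

## 5. The synthetic cohort: what it emulates, and what it does not

The generator (`generate_cohort()`, `generate_proteome()`,
`generate_cytokines()`) encodes the study conditions the analysis assumes:

* three latent phenotypes with day-1 prevalences 202/384, 156/384, 26/384;
* a severe phenotype C (hepatic failure pattern: transaminases ~50× the
  reference location, INR ~2.5×, lactate ~7×, platelets ~0.4×) and an
  intermediate renal phenotype B (creatinine elevated, urine output
  reduced, older patients);
* right-skewed laboratory values drawn log-normal, pressures and blood-gas
  values normal, on natural scales (U/L, mmol/L, mmHg) —
  median-and-IQR-style skew comes out of the distribution family;
* 1 + Poisson(2) repeat measurements per variable-day; MCAR missingness at
  10% per patient-day-variable (below the 30% retention filter; the
  missingness mechanism is a deliberate simplification — a hook for
  informative missingness would change `generate_cohort()` only);
* day-to-day transitions on the 1/4/7/10 grid with absorbing
  death/discharge, phenotype B the most mobile (0.35 per-step probability
  of moving to A), and cluster-graded mortality (0.29/0.45/0.92): in-grid
  deaths come from the transition rows; survivors of the grid die by day
  30 with the probability attached to their last latent state;
* a 609-protein log-normal (log2-Gaussian) intensity matrix with additive
  per-batch offsets and three designated regulated sets: a 60-protein
  complement/coagulation gradient decreasing A→B→C, a 25-protein liver
  leakage set high in C, a 15-protein low-molecular-weight renal set high
  in B;
* 13 cytokines clamped at assay quantification limits (below LLOQ → 0,
  above ULOQ → ULOQ). The default ULOQ caps are set so that strongly
  induced analytes (IL-6, IL-8, IL-18) exceed them in a realistic fraction
  of severe patients — an upper-clamp rule that could never fire would be
  untestable dead code.

**One deliberate calibration.** Within a phenotype the generator draws
variables independently. Real clinical variables co-vary strongly with
severity, so a literal translation of published median ratios into
independent per-variable shifts under-separates the intermediate phenotype:
the multivariate (Mahalanobis) distance of the real clusters is larger
than the product of its marginals suggests. The default location shifts of
phenotype B are therefore set to twice the ratio-derived z-shifts,
restoring a separation at which the three-cluster structure is detectable
by silhouette — the regime the analysis is designed for. The generator
aims at qualitative ordering of the marginals, not at reproducing any
published table.

**What passing tests do not show.** The generator has no within-patient
autocorrelation beyond the latent state, no informative missingness, no
inter-variable correlation within phenotype, no measurement drift, and its
phenotypes are true Gaussian/log-normal mixtures. Recovery results
(adjusted Rand index ≥ 0.7 across seeds, silhouette selecting k = 3) are
statements about the pipeline's correctness under its own assumptions —
not evidence that three clusters exist in any particular hospital's data.

## 6. Problem sizes used by the test suite

Chosen to exercise each property at the smallest scale that makes the
statistics meaningful: cohorts of 384 patients (the study-sized default)
for clustering recovery over 20 seeds; n = 10,000–20,000 single-day
cohorts with a 3-variable catalogue for prevalence/transition frequency
checks; 50 replicates of 500-protein null matrices (3 × 20 samples) for
the dual-criterion type-I rate; 100,000 label permutations for the Tukey
oracle; and reduced MCCV configurations (8–15 outer, 5–8 inner iterations,
80–150 trees) for the classifier's behavioural tests. Chance-level checks
pool several independently shuffled datasets, because a single finite
dataset retains O(1/√n) spurious feature–label association that no number
of cross-validation iterations can remove.

## 7. Known limitations

* Batch normalization corrects location only; scale or nonlinear batch
  effects pass through.
* The Shapley estimator is Monte-Carlo: rankings of nearly tied features
  are noisy at small `shap_nsim`; the median over inner iterations is the
  stabilizer.
* `silhouette_select_k` computes a full distance matrix — fine for
  cohort-scale n, wrong tool beyond ~10⁴ rows.
* The trajectory model has no notion of interval censoring: a death
  between assessment days is recorded at the following grid day.
* One plasma sample per patient (day 1) in the synthetic proteome; the
  screen itself is timepoint-agnostic, but multi-timepoint generation
  would be an extension of `generate_proteome()`, not of the statistics.
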