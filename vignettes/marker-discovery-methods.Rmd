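---
title: "Methods: LOOCV-embedded marker screening for two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LOOCV-embedded marker screening for two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uromarker)
```

## The problem

Untargeted GC-MS urine metabolomics yields a peak table: integrated
chromatographic peak areas for hundreds of compounds across samples, with a
large fraction of exact zeros because many compounds fall below the
instrument's detection limit in any given sample. Given such a table for two
clinical groups — here, early-stage (non-muscle-invasive) bladder cancer
cases against hernia controls — the task is to select a small set of
compounds whose abundance reliably discriminates the groups, to attach a
classifying threshold to each, and to verify both the single markers and a
combined panel on samples that played no role in selection.

`uromarker` implements that workflow end to end: cohort splitting,
multivariate separation diagnostics (PCA, OPLS-DA), a leave-one-out
cross-validated two-phase univariate screen, marker-set stabilisation by
intersection, threshold selection, and a logistic-regression panel with
independent-cohort evaluation. A seeded simulator generates study-shaped
peak tables so that the whole chain is testable without any external data.

## Data model

A `profile_matrix` stores compounds x samples abundances, per-compound
metadata (name, nominal mass, metabolite annotation or `"unknown"`, a
contaminant flag) and per-sample `case`/`control` labels. Abundances are
non-negative; **exactly zero means "not detected"**. Import treats empty
cells, `NA` and `0` identically, imputing all of them to zero, so the matrix
is total after loading. Zeros are data, not missingness, for every
downstream computation: the detection filter counts them directly and the
rank-based test handles the resulting ties.

`split_cohorts()` allocates a discovery cohort of the requested size
proportionally to group size with largest-remainder rounding, then draws a
seeded simple random sample within each group. Proportional allocation of 63
cases and 61 controls into a 100-sample discovery cohort gives 51 cases and
49 controls, leaving 12 + 12 for independent testing. The rounding is
deterministic; only the membership is random. We adopted the deterministic
reading of "sampling proportional to size" because it is the only one that
pins down the per-group counts; a fully stochastic PPS draw would make the
counts themselves random variables, which would leak split noise into every
downstream comparison.

## The two-phase screen

Per compound, phase 1 tests the case and control abundances with the
two-sided **Wilcoxon rank-sum test** and keeps compounds with
`p < alpha / m`, the Bonferroni threshold over all `m` compounds tested
(`0.05 / 922 = 5.42e-5` in the motivating study's shape). `m` is always the
full compound count, not the count of survivors of any earlier step — this
is what makes the threshold reproducible and the family-wise error bound
valid. Phase 2 keeps phase-1 survivors detected (abundance > 0) in strictly
more than 60% of the case samples; a compound that is differential only
because it is *absent* in cases cannot be a practical urine marker.

The rank-sum p-value uses the exact Mann-Whitney null distribution when the
pooled sample has at most 20 untied values, and otherwise the normal
approximation with tie correction and continuity correction. The exact
branch is checked in the test suite against full enumeration of all
case/control relabelings up to pooled size 10, and the approximate branch
against the reference implementation in `stats::wilcox.test`.

A **Shapiro-Wilk gate** (`shapiro_wilk_gate()`) reports per-compound,
per-group normality p-values and a dataset verdict. It is advisory only:
zero-inflated peak tables essentially always reject normality, and the
pipeline is unconditionally nonparametric. Compounds constant within a group
(typically all-zero) get an undefined p-value there and are recorded, not
fatal.

Demographics tables (2x2 counts such as gender or hematuria by diagnosis)
are compared with `compare_categorical()`: Pearson chi-square on 1 df
*without* continuity correction. On the motivating study's gender table the
uncorrected p (0.00045) matches the reported 0.0005 to within one unit of
the printed digit, while the Yates-corrected value (0.0011) does not.

## LOOCV and marker stabilisation

`discover_markers()` wraps the full loop. For each of the n discovery
samples, the two-phase screen is refit on the other n-1 samples; every
surviving candidate receives a classifying threshold selected on those
training samples; and the held-out sample is predicted *case* iff its
abundance reaches the threshold. The detection filter is computed on the
round's n-1 training case samples rather than the full cohort — leave-one-out
hygiene; the difference is at most one sample. This yields n candidate lists
and n held-out predictions. The stable marker set is the intersection of all
n lists, minus compounds flagged as GC-MS background contaminants
(`is_contaminant` in the metadata, optionally populated from name patterns
via `flag_contaminants()`, e.g. siloxane-like derivatives). Exclusion after
intersection and exclusion before it give the same set; we exclude after.
Per-marker LOOCV accuracy, sensitivity and specificity pool the n held-out
predictions.

Two implementations of the round statistics exist. The default
(`method = "incremental"`) precomputes, per compound, the full-cohort
Mann-Whitney U, each sample's pairwise contribution to it, and each sample's
tie-group size; a round's statistic is then recovered exactly by subtraction,
turning the LOOCV screen from O(m n^2 log n) into O(m n log n). The direct
re-ranking path (`method = "direct"`) is retained and the suite asserts exact
(`identical()`) agreement, including at small n where the exact rank-sum
branch is active.

### Thresholds

Classifying thresholds maximise **Youden's J** (sensitivity + specificity -
1) over the ROC operating points, with ties broken by higher specificity and
then higher threshold — in a screening context a false positive sends a
patient to cystoscopy, so specificity is the natural tie-break. The returned
threshold is the midpoint between the adjacent distinct abundances the
chosen operating point separates: any cutoff strictly between those two
values classifies identically, and the midpoint is the representation most
robust to instrument jitter. The direction "higher abundance implies case"
is fixed: the workflow targets up-regulated urine markers. Round-specific
thresholds are refit within each LOOCV round; the final reported threshold
per marker is fit on the whole discovery cohort and is the one applied to
the independent test cohort.

## The logistic panel

`fit_logistic_panel()` fits a binomial GLM with logit link on the raw
abundances of the selected markers plus an intercept. Because stable markers
are nearly absent in controls, the discovery cohort is often perfectly or
almost perfectly separated, where the unpenalised MLE diverges; a small
ridge penalty (default `1e-6 * n`) keeps the fit finite without materially
biasing coefficients away from the MLE in non-separated data. The penalty is
applied to the *standardised* coefficients so its meaning does not depend on
abundance units; reported coefficients are mapped back to the raw scale
(log-odds per abundance unit). The test suite verifies that as the ridge
goes to zero on non-separable data the fit satisfies the unpenalised score
equations to gradient norm below 1e-6 and matches `stats::glm`. Features
enter untransformed by default; `log1p_transform = TRUE` is available since
peak areas span orders of magnitude, but the default follows the plain
reading of the original analysis. `evaluate_markers()` applies the
discovery-derived per-marker thresholds and the panel to the held-out test
cohort and returns the test ROC.

## PCA and OPLS-DA diagnostics

Both operate on the samples x compounds matrix after **autoscaling**
(mean-centering and unit-variance scaling per compound) — the default of the
R OPLS implementations conventional in this field; Pareto scaling is
available via `scaling = "pareto"`. Zero-variance compounds are excluded
from PCA with a warning. PCA's R2X is the variance fraction of the retained
components.

OPLS-DA uses the orthogonal-projections NIPALS algorithm with the centered
-1/+1 class coding: each orthogonal component captures X-variation
uncorrelated with the class, is deflated, and a single predictive component
is extracted last (one predictive component is the correct count for a
binary response). R2Y is the explained response variance of the training
fit. Q2 = 1 - PRESS/TSS is estimated by stratified 7-fold cross-validation
(seeded; fold count configurable), refitting everything — including the
scaling — inside each fold. Q2 at or below zero means no predictive power;
the suite checks that the mean Q2 over label permutations of structureless
data is non-positive, and that predictive and orthogonal scores are
orthogonal to numerical tolerance (1e-8 after centering). Q2 < R2Y is
typical but not asserted: it can legitimately fail.

The printed R2X/R2Y/Q2 of the motivating study are properties of its real
922 x 124 matrix, which is not deposited in a machine-readable archive;
they are therefore not reproduction targets here, and the study did not
state its scaling or fold count either.

## The simulator

`simulate_profile()` models each cell as *Bernoulli detection x log-normal
abundance*, then censors everything below a hard `detection_limit` to zero —
the simplest mechanism consistent with zero-inflated peak tables and an
instrument cutoff. Defaults define the study-shaped conditions used
throughout the tests:

| parameter | default | rationale |
|---|---|---|
| `n_case`, `n_control` | 63, 61 | the study's cohort sizes |
| `m_compounds` | 922 | the study's compound count |
| `n_markers`, `n_contaminants` | 8, 8 | eight reported markers; a comparable number of background species |
| `log_mu`, `log_sigma` | log(1e4), 1 | abundances on the 1e3–1e5 peak-area scale of the reported thresholds |
| `marker_log_shift` | 3 | a 3 log-sd up-shift in cases: "high in cancer" |
| `detect_p_case` | 0.9 | markers detected in most case samples |
| `detect_p_control_marker` | 0.02 | "nearly not detected" in controls |
| `detect_p_background` | 0.5 | heavy but unstructured missingness |
| `detect_p_contaminant` | 0.95 | contaminants present everywhere |
| `detection_limit` | 700 | the instrument's peak-area cutoff, modelled abstractly |

The generator emulates the *statistical* structure the pipeline relies on —
zero inflation, group-differential detection, contaminants identical across
groups — and nothing chromatographic: no retention-time structure,
co-elution, batch drift or abundance correlation between compounds. Passing
tests on simulated data therefore demonstrate that the algorithms recover
planted structure under the stated noise model; they are not evidence about
any particular real cohort, where effect sizes are smaller and compounds are
correlated. With the default 3 log-sd shift the planted markers are
recovered with precision = recall = 1; the suite also runs a null control
(no planted markers, 200 seeds) confirming that the Bonferroni screen keeps
its family-wise error and that the 100-fold intersection almost never emits
a non-empty marker set by chance.

## Numerical choices and degenerate inputs

* Rank-sum: exact branch only for untied pooled samples of size <= 20;
  continuity correction always applied in the normal branch; all pooled
  values identical gives p = 1.
* ROC/AUC: trapezoidal area, which equals pairwise concordance with ties
  counted one half (asserted to 1e-12); single-class input is an error.
* Youden selection on all-identical scores returns J = 0 flagged
  `degenerate`.
* Logistic IRLS: Newton steps with step-halving on the penalised objective,
  at most 200 iterations, convergence on the penalised gradient norm;
  non-convergence is an error, never a silent result.
* OPLS-DA: an orthogonal component with negligible norm (< 1e-12) stops the
  orthogonal extraction early; zero-variance compounds get scale 1 inside CV
  folds (they are centered to zero and carry no weight).
* `split_cohorts` rejects allocations that would empty a group in either
  cohort; LOOCV requires at least two samples per group so no round loses a
  group.

## Problem sizes used in the checks

The packaged tests and the acceptance script use the study-shaped
922 x 124 simulation for end-to-end runs (single-run discovery takes on the
order of a second with the incremental LOOCV path), 200 seeds for the null
control, 50 label permutations for the Q2 null, and full enumeration up to
pooled n = 10 for the exact-test oracle. These sizes give binomial/standard
error tolerances that the assertions state explicitly.

## Worked example

```{r example}
sim <- simulate_profile(synthetic_config(seed = 1))
split <- split_cohorts(sim$pm, discovery_size = 100, seed = 1)
pm_disc <- subset_samples(sim$pm, split$discovery_ids)

fit <- discover_markers(pm_disc)
print(fit)

ev <- evaluate_markers(fit, subset_samples(sim$pm, split$test_ids))
ev$per_marker
ev$panel_roc$auc
```

## Known limitations

* Contaminant identification is a metadata flag (optionally from name
  patterns), not an algorithm; the original curation was manual.
* The panel ROC on the discovery cohort uses in-sample predicted
  probabilities, the plain reading of the original figures; an
  out-of-sample (LOOCV) panel ROC would be smaller and is not implemented.
* Single-marker classifiers assume up-regulation in cases; down-regulated
  markers would need a direction parameter.
* Q2 is reported for the one-predictive-component binary model only; no
  multi-class OPLS-DA, no VIP scores.
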