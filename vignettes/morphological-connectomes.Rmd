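---
title: "Morphological grey-matter connectomes: model, thresholds, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological grey-matter connectomes: model, thresholds, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmconnect)
```

## The analysis in one paragraph

A morphological grey-matter (GM) connectome is a single-scan brain network:
nodes are cortical parcels from a fixed atlas (q = 68 for FSAverage, q = 360
for Glasser 2016), and the edge weight between parcels *i* and *j* is the
Manhattan dissimilarity of their morphometric features — with the default
single feature, `A[i, j] = |thickness_i - thickness_j|` in millimetres.
Because raw dissimilarity graphs are complete, each is binarized by
*proportional thresholding*: the cutoff `phi` is the `tau`-th percentile of
the edge-weight distribution pooled over **all** scans in the set, so one
absolute cutoff applies to every scan and inter-scan differences in edge
counts remain meaningful. Each binarized graph is summarized by six global
metrics — density D, degree assortativity r, transitivity T, global
efficiency Eg, average (unnormalized) betweenness centrality BC, and
modularity Q of a greedily detected partition. These six numbers per scan
feed (a) a mixed-effects logistic comparison of multiple sclerosis (MS)
clinical profiles (CIS, RR, PP, SP) and (b) a majority-voting ensemble of
four classifiers evaluated under patient-grouped stratified
cross-validation, with `tau` itself treated as a tunable hyperparameter.

## The synthetic cohort generator

Clinical MRI cohorts of this kind are not publicly distributable, so the
package ships a generator whose defaults emulate the structure of a
reference longitudinal MS cohort: 90 patients (12 CIS, 30 RR, 20 PP, 28 SP)
contributing 652 scans (64, 233, 140, 215), scanned 6-monthly for three
years and then yearly. Observed scan totals imply attrition, so per-patient
scan counts are drawn from a truncated Poisson matched to each group's mean
and adjusted to reproduce the group totals exactly, rather than imposing
the idealized 11-visit protocol.

Thickness of ROI *i*, patient *p*, time *t* (years):

$$x_{pit} = \mu_i - a(g_p, i) - \rho(g_p)\, t + b_p + \varepsilon_{pit},
\qquad b_p \sim N(0, \sigma_s^2),\ \varepsilon \sim N(0, \sigma_e^2)$$

* `mu_i` — baseline thickness; the default profile is the set of normal
  quantiles `qnorm(ppoints(q), 2.6, 0.4)` (≈1.6–3.6 mm at q = 68), inside
  the physiologic 1–5 mm band, emulating the bell-shaped spread of parcel
  mean thickness over a real cortex. The shape is not cosmetic: for a 1-D
  feature, a triangle in the thresholded dissimilarity graph requires three
  values pairwise at least `phi` apart, i.e. a spread of at least `2*phi`,
  so a narrow or uniform profile makes high-threshold graphs structurally
  triangle-free and transitivity degenerate; a tailed profile keeps all six
  metrics informative over the whole threshold grid. A flat baseline makes
  every connectome the zero matrix (a property the tests exploit).
* `a(g, i)` — profile-specific atrophy: each profile thins a fixed fraction
  of ROIs by a fixed depth. Affected sets are *nested* across profiles
  (one seeded ROI permutation, each profile takes its leading fraction), so
  atrophy burden is ordered CIS < RR < SP ≲ PP, matching the clinical
  picture that GM alteration grows with progressive disease. Defaults:
  CIS 5% of ROIs by 0.05 mm, RR 15% by 0.12 mm, SP 30% by 0.25 mm, PP 30%
  by 0.30 mm.
* `rho(g)` — longitudinal thinning, 0.005 / 0.010 / 0.020 / 0.020 mm/year
  for CIS / RR / SP / PP; magnitudes of published annual cortical-thinning
  estimates in MS.
* `sigma_s = 0.10` mm between-patient intercept sd, `sigma_e = 0.05` mm
  within-scan measurement sd — measurement error of FreeSurfer-style
  thickness estimates is of order a few hundredths of a millimetre, while
  between-subject anatomical variation is larger.
* Ages and sex ratios per profile follow the reference cohort's Table-level
  summaries (e.g. CIS 32.4 ± 6.4 years, 47% female).
* Values are clipped at 0.5 mm so the distance metric always sees positive,
  physical thicknesses.

What the generator does **not** emulate: spatial smoothness of atrophy maps
(affected sets are random ROI subsets), lesions, scanner effects, spatial
correlation of measurement noise, or any real atlas geometry. Passing tests
therefore demonstrate that the pipeline's statistics behave correctly under
a faithful covariance structure (within-patient correlation, group effects,
noise), not that real MS cohorts will show the same effect sizes.

## Numerical choices

* **Quantile definition.** `phi` is the linearly interpolated empirical
  quantile (order-statistic position `1 + tau*(n-1)`, R type 7). Fixing the
  definition makes `phi` bit-reproducible; the pooled retained fraction
  then equals `1 - tau` within `1/length(pooled)`.
* **Ties at the cutoff.** An edge with weight exactly `phi` is retained
  (binarization keeps `w >= phi`), the strict reading of dropping only the
  weaker connections.
* **Pooling uses the strict upper triangle only.** The diagonal is
  structurally zero and, pooled, would distort low percentiles.
* **Betweenness is unnormalized** and averaged over nodes, counting each
  unordered pair once with endpoints excluded — at q = 68 typical values
  are in the tens, at q = 360 in the hundreds, which is the scale on which
  the reference analyses report BC.
* **Community detection** for Q uses deterministic greedy agglomerative
  modularity maximization (Clauset–Newman–Moore, via igraph). Louvain-type
  algorithms are seed-dependent; a deterministic merge sequence makes Q a
  reproducible feature. Q of the detected partition never exceeds the
  exhaustive-search maximum (asserted on small graphs in the tests).
* **Undefined metrics are flagged, never zeroed.** Assortativity is
  undefined when endpoint degrees are constant (complete or empty graphs);
  modularity is undefined on edgeless graphs. Downstream, classification
  imputes them with the training-fold mean (0 is a valid assortativity
  value and must not be fabricated); the CV sweep excludes them per cell
  with a logged count.
* **Disconnection** at high `tau` is handled with the `1/Inf = 0`
  convention in Eg, and betweenness is computed per component.

## The group comparison model

For each metric and profile pair, the group indicator is regressed on the
(z-scored) metric with age and sex as covariates, binomial family, logit
link; `scan_time` can be added as an optional covariate, and the reported
p-value is the Wald test on the metric coefficient.

How the longitudinal design enters was a genuinely open design choice, and
the obvious option turns out to be broken. A scan-level mixed logistic with
a per-patient random intercept (the `xtmelogit`-style analysis) looks
natural, but here the outcome — the clinical profile — is *constant within
patient*. In that regime the random-intercept variance is only weakly
identified and its estimate runs to the boundary (σ̂ → ∞, each patient fit
perfectly by its own intercept); the fixed-effect standard error inflates
with it and the Wald test becomes severely conservative — under patient-level
label permutations of a null cohort its rejection rate at α = 0.05 drops
to ~0.01–0.02 and the p-value distribution piles up near 1. Averaging each
patient's scans and fitting an ordinary logistic GLM on patient-level
observations is the likelihood-appropriate reduction (with a
cluster-constant outcome, the patient mean carries all the between-group
information), and the same permutation study shows it calibrated (rejection
rate ≈ 0.03–0.06). `compare_pair()` therefore defaults to
`unit = "patient"`; the mixed model remains available as `unit = "scan"`
for sensitivity analyses.

Two further caveats are built in. First, when the metric (nearly) separates
the groups, the Wald statistic degenerates — coefficient and standard error
diverge together and p tends to 1 regardless of the evidence (the
Hauck–Donner effect); `compare_pair()` detects this (SE > 100 on the
z-scored predictor, or fit failure) and falls back to the likelihood-ratio
test against the covariate-only model, recording the route in the `method`
column. Second, one model is fitted per metric per pair with no
multiplicity correction by default (matching the per-metric star
annotations such analyses report); a Bonferroni flag is available.

## Classification protocol

Folds are patient-grouped and profile-stratified: all longitudinal scans of
a patient travel together, so no identity leaks across train / validation /
test; a leakage assertion runs on every experiment. Within each of the k =
10 folds, the non-test patients are split 80/20 into training and
validation. For every candidate `tau` the cutoff is recomputed **from
training scans only**; per learner, the (hyperparameters, `tau`) grid point
maximizing validation F1 is selected, ties broken toward the smaller model
(grids are ordered small-to-large and the first maximum wins). The chosen
configuration is then refit on train + validation (cutoff recomputed on
those scans; the test set never enters any pooled distribution) and scored
on the held-out test patients. Features are standardized and undefined
metrics mean-imputed using training statistics only. Class weights are
inverse class frequency on scan counts, countering the profile imbalance.

The four base learners are ridge-penalized logistic regression (glmnet,
`lambda = 1/C`), random forest (ranger), an RBF SVM with Platt-calibrated
probabilities (e1071), and discrete AdaBoost (SAMME) over depth-1 rpart
stumps, implemented in the package since no AdaBoost implementation is
available in the dependency set. Default grids place three points per
interval endpoint-to-endpoint (e.g. LR C in {1, 10, 100}); `tau`'s default
grid spans the informative 0.6–0.8 range with the full 5%–95% grid
available. The ensemble takes the modal vote; 2–2 ties go to class 1 iff
the mean predicted probability exceeds 0.5; the ensemble probability (used
for rank-statistic ROC-AUC) is the mean of the four probabilities. Scans
are the prediction unit, matching scan-count-driven report tables.
Experiments are compared fold-by-fold with the two-sided Wilcoxon
matched-pairs signed-rank test (identical reports return p = 1 by
convention).

Open protocol points were resolved as follows: "repeated 10 times and
averaged" is implemented as aggregation over the 10 folds (mean and sd),
with independent repeats available by rerunning under different seeds; AUC
uses mean ensemble probabilities rather than vote fractions; the refit
after selection uses train + validation.

## Problem sizes used in the validation suite

The packaged tests exercise: metric equivalence against brute-force oracles
(Floyd–Warshall distances, triangle triple loops, explicit shortest-path
enumeration, exhaustive partition search) on 200 random graphs with
q in [4, 9]; the quantile-retention law and edge-set nestedness on a
500-scan cohort at q = 68 over the full 5%–95% grid; null calibration of
the ensemble (20 seeds, 30 vs 30 patients, q = 68, AUC expected near 0.5)
and of the mixed model (200 patient-level label permutations); and
planted-effect recovery across atrophy depths {0, 0.2, 0.5} mm. These sizes
were chosen as the smallest designs in which the targeted properties are
statistically identifiable.

## Known limitations

* The generator's atrophy is spatially unstructured; topological signatures
  that depend on contiguous atrophic regions are out of reach.
* Metric values on synthetic cohorts need not match real-cohort magnitudes;
  only distributional and inferential properties are asserted.
* The CV-sweep shape (stability of BC and r near tau 0.7–0.8, variability
  blow-up of Eg and T beyond 0.7) is reproduced qualitatively on synthetic
  data; exact CV magnitudes depend on the cohort.
* No weighted-graph metric variants, nodal metric maps, or small-world
  sigma; no 4-way multiclass classification or resampling schemes.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  cohort = cohort_config(
    n_patients = c(CIS = 5, RR = 5, PP = 5, SP = 5), n_scans = NULL,
    mean_scans_per_patient = c(CIS = 3, RR = 3, PP = 3, SP = 3),
    q = 68),
  experiments = list("RR:PP", "CIS+RR:PP+SP"),
  seed = 1
)
record <- run_pipeline(cfg, "gm-out")
readr::read_csv("gm-out/group_stats.csv")
```
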