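---
title: "Normative modelling of multi-scanner PET parametric maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of multi-scanner PET parametric maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petnorm)
```

## The model and its assumptions

`petnorm` treats each grey-matter voxel of a parametric PET map
(dopamine-synthesis Ki in 1/min, or unitless BPND) as an independent
regression problem on a reference cohort of healthy controls. The
per-voxel model is Bayesian linear regression with an isotropic
Gaussian weight prior whose precision is chosen by maximizing the
marginal likelihood (type-II maximum likelihood) — the standard
construction for "non-informative" normative models. The optimizer is
derivative-free (Nelder–Mead over log precisions, initialized at
`(0, log(1/var(y)))`), which is robust to the flat likelihoods of
noise-only voxels.

Assumptions worth keeping in mind:

* **Gaussian residuals per voxel.** Deviation scores are Z-scores
  against a Gaussian posterior predictive. Skewed tracer distributions
  are not warped; strongly non-Gaussian voxels will show mis-calibrated
  tails.
* **Linear covariate effects.** Age, sex and optionally BMI enter
  linearly; continuous covariates are standardized by *reference*
  statistics, stored in the model so patient designs reuse them.
* **Per-voxel independence.** No spatial regularization is applied at
  fit time; spatial structure re-enters only through TFCE and cluster
  inference.
* **Linear scanner effects.** ComBat assumes additive/multiplicative
  batch effects; nonlinear scanner differences (different point-spread
  functions, reconstruction kernels) are out of scope.

The predictive SD includes the parameter-uncertainty term
`x' A^{-1} x`. At the cohort sizes typical of PET (tens of subjects)
this matters: dropping it inflates extreme-deviation counts in held-out
subjects. With it, the model is slightly conservative at small n
(Gaussian rather than Student-t predictive), which shows up as held-out
tail fractions a shade above the asymptotic 2.28% per tail.

A voxel where the response has zero variance, or where the optimizer
fails, is flagged non-converged; its Z-scores are NA sentinels and
every downstream summary excludes it from both numerator and
denominator.

## Harmonization

Two strategies sit behind one surface:

* **ComBat** (`fit_combat()`/`apply_combat()`): the parametric
  empirical-Bayes location/scale adjustment from genomics. The fit is
  estimated on controls only and then applied unchanged to patient
  cohorts from the same scanners, so patients never influence batch
  estimates and genuine disease effects are not absorbed as scanner
  effects (they shift with the data through the standardization, not
  the batch parameters). Declared covariates are estimated jointly and
  preserved. The EB iterations stop at a relative change below 1e-4 or
  100 iterations. Only the parametric variant is implemented; the
  in-package implementation agrees with the reference genomics
  implementation to ~1e-14 when fitting and applying on the same data.
* **Gaussian smoothing** (`gaussian_smooth()`,
  `select_smoothing_kernel()`): isotropic convolution with
  `sigma = FWHM / (2 sqrt(2 ln 2))`, computed as a separable
  zero-padded convolution with mask renormalization (out-of-mask voxels
  are treated as absent, so a constant field is exactly invariant). The
  kernel is chosen from a candidate grid by matching the pooled-value
  SD of the smoothed target to the reference (a Kolmogorov–Smirnov
  criterion is available as an alternative). Smoothing can only match
  dispersion; it provably cannot remove an additive scanner offset,
  which is why the package's default pipeline harmonizes with ComBat.

`residual_scanner_effect()` quantifies what is left: per-subject
distribution moments compared across scanners with Mann–Whitney (two
batches, rank effect size r = |Z|/sqrt(N)) or Kruskal–Wallis
(eta-squared).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Grey-matter probability threshold | 0.30 (inclusive `>=`) | trade-off between coverage and PET resolution |
| Extreme-deviation threshold | Z = 2 (strict `>`) | two predictive SDs; chance 2.5%/tail, 5% total |
| Cross-validation folds k | 5 | control scoring without a held-out cohort |
| EXPV analysis threshold | 0.03 (`>`; `>=` at 0.10) | voxels where covariates explain a meaningful fraction |
| Permutations | 500 at desk scale (5000 full scale) | FWE resolution vs runtime |
| TFCE | E = 0.5, H = 2, dh = max/100, 26-connectivity | standard published defaults |
| Minimum cluster size | 50 voxels | reporting convention |
| Smoothing candidates | 0–6 mm grid | the selection criterion picks within it |

## The synthetic cohort generator

No public PET cohorts with the required structure exist (the data this
analysis style targets are available only on request), so the package
ships a first-class generator, `cohort_spec()`/`generate_cohort()`,
that emulates the statistical structure the pipeline assumes:

* voxel intensities `y = mu_v + a_v (age-40) + s_v sex + b_v (bmi-25) +
  g_batch + theta * D_group + d_batch * sigma * eps`;
* a striatum/cortex toy atlas; baseline Ki-like values (0.008/min
  background, 0.012/min striatum, noise SD 0.0015/min);
* covariate effects sized so age+sex explain ~10–12% of voxel variance,
  in the range reported for dopamine-synthesis maps;
* per-scanner additive shifts and noise-scale factors;
* patient deviation fields: positive striatal for FEP-like cohorts,
  negative cortical for chronic-SCZ-like cohorts, with per-subject
  magnitudes `theta ~ N(theta_bar_g, tau_g^2)`;
* PANSS totals increasing in theta (minimum 30 = 7+7+16, subscales
  split ~30/25/45% of the excess), giving the correlation structure the
  clinical analyses assume;
* response labels from a threshold rule on theta with a 5% label-flip
  probability — responders carry larger striatal deviations, the
  premise of the classification analysis.

The default reference is 50 controls over two scanners (at least 10 per
scanner), the recommended minimum for this class of model. Effect sizes
for cortical deviations in chronic cohorts are free parameters of the
generator, chosen once at plausible magnitudes (≈1.3–1.7 noise SDs);
they are not calibrated to any published effect.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spatially correlated acquisition noise,
partial-volume effects, nonlinear scanner differences, non-Gaussian
tracer distributions, motion artefacts, and dataset-specific response
definitions (a single thresholded-deviation rule stands in for the
heterogeneous clinical criteria real studies use).

## Statistics

* **Scheirer–Ray–Hare**: joint ranking (average ties), sequential
  ANOVA sums of squares on ranks, `H = SS_effect / (SS_total/(N-1))`,
  chi-squared p. With a single-level second factor this reduces exactly
  to tie-corrected Kruskal–Wallis, which is the package's algebraic
  cross-check.
* **Permutation GLM** (`permutation_glm()`): per-voxel F tests with
  Freedman–Lane residual permutation under the nuisance model;
  family-wise error from the permutation distribution of the image-wise
  maximum of the (optionally TFCE-enhanced) statistic, with the
  `(1 + #{max >= obs}) / (1 + B)` estimator so p is never zero.
  Interaction terms are tested by permuting residuals under the
  main-effects model. Results are deterministic under a fixed seed.
* **TFCE** is implemented in C++ as a threshold sweep (left Riemann
  sum, step `max/100`) over connected components; at that step the
  uniform-cluster closed form `e^0.5 h^3 / 3` is reproduced within 1%.
* **Risk ratios** pool voxel-subject pairs per group into a single 2×2
  table (the reading consistent with one table per sign); the
  averaged per-subject-rate variant is also returned. Wald CIs on the
  log scale; a +0.5 continuity correction on all cells is applied and
  flagged only when a zero cell occurs.
* **Mann–Whitney** uses the tie-corrected normal approximation without
  continuity correction by default, so its p agrees exactly with the
  k = 2 Kruskal–Wallis chi-squared p; a `correct` flag enables the 0.5
  correction, which tracks the exact enumeration p better below n ≈ 10
  per group. Effect-size CIs are bootstrap percentile intervals.
* **ROC/AUC** is the rank (Mann–Whitney) estimator with ties counted
  half, reported always for the stated positive class with an explicit
  direction tag, plus a DeLong structural-component SE and Wald CI.
  `delong_compare()` is the paired DeLong test, returning the full AUC
  covariance.

## Numerical choices and degenerate inputs

* Masked vectors use x-fastest (R column-major) flattening, 0-based
  voxel indices in cluster tables; maps are float64 in memory, float32
  NIfTI-1 on disk (sform code 2 carries the affine).
* BLR uses a one-time eigendecomposition of X'X shared across voxels,
  making each per-voxel optimization O(p) per objective evaluation.
* Single-batch ComBat is the identity; zero-variance voxels error at
  harmonization (no batch model is estimable) and are flagged (not
  thrown) at model fit.
* Kernel-selection ties break toward the smaller kernel; `fwhm = 0` is
  the exact identity.
* Empty cluster sets are valid results; `p_FWE` floors at `1/(1+B)`.
* The pipeline derives per-stage seeds deterministically from one
  master seed; re-running a config reproduces all numeric artifacts
  bitwise (verified by manifest checksums).

## Problem sizes

The packaged analyses run at desk scale, chosen so the full suite
completes in minutes on one CPU: a 16^3 grid (4096 voxels) for
end-to-end runs, 200 reference / 100 held-out subjects for calibration,
500-permutation stat maps, and 200 replicates of 1000 voxels for the
family-wise-error calibration. Full-scale use (~200k grey-matter
voxels, 5000 permutations) is a configuration change, not a code path
change; fitting scales linearly in voxels and the permutation GLM in
voxels × permutations.

## Known limitations

* Gaussian-only likelihoods; no warped or hierarchical (site-as-random-
  effect) variants.
* ComBat linearity; no ComBat-GAM.
* The held-out tail calibration is slightly below the nominal 2.5%/5%
  chance levels because the Gaussian predictive understates t-tails;
  the gap shrinks with reference size.
* Overlap maps and risk ratios inherit any residual mis-calibration of
  Z multiplicatively; compare groups scored with the same model rather
  than absolute percentages across models.
* The permutation GLM assumes exchangeable subjects under the nuisance
  model; no exchangeability blocks (e.g. per-site restriction) are
  implemented.
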