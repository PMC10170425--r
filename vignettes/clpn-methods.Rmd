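---
title: "Cross-lagged panel networks for ordinal distress data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for ordinal distress data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`clpnet` estimates directed *cross-lagged panel networks* (CLPN) from
two-wave panel data of ordinal symptom items. For items
$y_1, \dots, y_p$ measured at waves $t$ and $t+1$, each item at $t+1$ is
regressed on **all** $p$ items at $t$:

$$ y_j^{(t+1)} = \beta_{j0} + \sum_{i=1}^{p} W_{ji}\, y_i^{(t)} + \varepsilon_j, $$

fitted by the LASSO,

$$ \hat W_{j\cdot} = \arg\min_\beta\; \tfrac{1}{2n}\lVert y_j^{(t+1)} - X^{(t)}\beta\rVert_2^2 + \lambda_j \lVert\beta\rVert_1 , $$

one regression per outcome node, so $W_{jj}$ is the *autoregressive* path of
symptom $j$ and $W_{ji}$ ($i \neq j$) the *cross-lagged* path from symptom
$i$ to symptom $j$, adjusted for the autoregressive effect and all other
symptoms. The L1 penalty sets weak coefficients exactly to zero, which is
what protects the network from spurious edges.

Node importance is summarized by *expected influence*: the signed sum of a
node's outgoing cross-lagged weights (out-EI, how strongly a symptom
predicts the others one wave later) and of its incoming weights (in-EI, how
strongly it is predicted). Signed sums are the defining property of expected
influence; taking absolute values would be a different (strength) index.

### Assumptions worth stating

* Ordinal Likert items (GHQ-12 on 0–3, loneliness on 1–3) are treated as
  continuous in the regressions. No polychoric machinery is used; this is
  the convention of the applied CLPN literature, and it means coarse,
  skewed items attenuate edge weights somewhat (see the simulation notes
  below).
* Predictors **and** outcomes are z-scored on the estimation sample before
  fitting, so edge weights are comparable across items with different
  scales. This is stated as an assumption: reported standardized
  coefficients do not identify whether the original analyses standardized
  outcomes too.
* With two waves, within-person and between-person variance remain
  entangled; a CLPN is a predictive description of wave-to-wave dynamics,
  not a within-person process model.

## Estimation choices

* **Solver.** Cyclic coordinate descent on precomputed Gram matrices, with
  an exact active-set refinement: after each sweep the stationarity system
  of the current active set is solved directly and accepted when the
  Karush–Kuhn–Tucker conditions hold, which gives solutions at solver
  precision and is what makes full-procedure bootstrapping affordable.
  Convergence tolerance 1e-7 on the largest coefficient change, at most
  1e5 sweeps (exceeding it is an error, not a silent stop).
* **Penalty grid.** Per node, 100 log-spaced values from $\lambda_{\max}$
  (the smallest all-zero penalty, $\max_i |\langle x_i, y\rangle|/n$) down
  to $0.001\,\lambda_{\max}$.
* **Penalty selection.** 10-fold cross-validation minimizing prediction
  MSE, rule `"min"` by default; `"1se"` is available. The original tooling's
  fold count and seed are unknown, so exact numeric reproduction of any
  particular published edge list is not attempted.
* **Folds.** Fold membership is a hash of the subject identifier and the CV
  seed, making estimates invariant to row order and keeping bootstrap
  duplicates of a subject in one fold.
* **Display threshold.** 0.05 on $|W|$ — strictly a display rule (strict
  inequality, entries exactly at 0.05 are kept). Centrality, bootstrap and
  comparison statistics always use unthresholded weights.

## The synthetic cohort

The panel data the method was built for (a UK household panel with GHQ-12
and a loneliness item, restricted access) cannot ship with the package, so
`default_true_model()` defines a generating process with the structure the
estimator assumes:

* a sparse VAR(1) over 13 latent variables: autoregressive diagonal 0.3 and
  ~20 cross-lagged paths with $|B| \in [0.10, 0.25]$ — the magnitude range
  of standardized edges typically reported for such networks; the
  wave-$t$ latent vector is z-scored before $B$ is applied, so $B$ lives on
  the same standardized scale as the estimator's coefficients and recovery
  can be read off directly;
* designated hubs: *loneliness* with the largest true out-EI and
  *feeling depressed* as the main recipient (largest in-EI), plus
  *worthless → confidence* as the single strongest path — echoing the
  qualitative structure reported for pandemic-era distress networks;
* innovation SDs $\sqrt{1 - \sum_i B_{ji}^2}$ (floored at 0.1), keeping
  latents near unit variance;
* ordinal measurement by fixed standard-normal quantile thresholds chosen
  so category frequencies are right-skewed like observed symptom data
  (e.g. ~70% of responses in the lowest category for *worthless*, ~65%
  "hardly ever" for loneliness);
* wave-level attrition (whole interviews, as in panel dropout) with
  logistic probability in sex, ethnicity and standardized age — the
  missing-at-random mechanism the imputation stage assumes. Item-level
  nonresponse is available as an option for imputation tests.

What the generator does **not** emulate: household clustering, survey
weights, mode effects, non-stationary threshold drift, any real-world
deviation from MAR, and the strong persistent common factor of real
distress batteries — the exchangeable wave-1 correlation fades at later
waves under the sparse VAR(1), so the synthetic battery's internal
consistency is moderate at wave 1 and lower afterwards, unlike real GHQ-12
data (α ≈ 0.9). Passing recovery tests on this cohort therefore shows
the pipeline is consistent for its own model class — not that any
substantive result about real populations is correct.

## Imputation

Missing interviews are imputed once by predictive-mean-matching chained
equations: each incomplete variable is regressed on all other item
variables plus the auxiliary covariates; coefficients are perturbed by a
normal draw (type-1 matching), the five observed cases with closest
predictions donate, and one donor's observed value is drawn uniformly.
Donor sampling guarantees imputed values are observed, in-range, ordinal
values. Variables are visited in ascending missingness order for 10 sweeps.
Multiple imputation is deliberately absent: pooled networks are not
well-defined, so a single completed dataset plus a complete-case
sensitivity analysis is the supported workflow. Age is included as an
auxiliary predictor by default (it predicts dropout); the stricter
sex-and-ethnicity-only convention is one configuration flag away.

## Resampling

* **Edge accuracy.** Nonparametric subject bootstrap; the penalty is
  re-selected inside every resample (fixing it would understate
  variability). 95% CIs are empirical 2.5/97.5 percentiles. Percentile CIs
  of LASSO estimates may exclude the point estimate; that is expected, and
  only `lower <= upper` is guaranteed.
* **Difference tests.** Two edges (or two nodes' expected influence) differ
  when the central 95% percentile interval of the bootstrapped difference
  excludes zero. No multiple-testing correction is applied across the
  thousands of pairs — the convention of this literature, and a caveat to
  keep in mind.
* **Stability.** Case-drop bootstrap: at drop proportions 0.1–0.7,
  subsamples without replacement are re-estimated and correlated with the
  full-sample centrality; the CS-coefficient is the largest proportion at
  which (and below which) at least 95% of subsamples correlate ≥ 0.7.

## Numerical notes and degenerate inputs

* Zero-variance items abort estimation with the item named; bootstrap
  resamples with zero-variance items are redrawn (at most 10 times, logged).
* Cronbach's α is `NA` (with a warning) when the sum score is constant; ω
  total comes from an iterated principal-axis one-factor fit (max 500
  iterations, tolerance 1e-6, loadings sign-fixed so their sum is
  non-negative) and is `NA` on non-convergence.
* Skewness and excess kurtosis are bias-adjusted (`G1`, `G2`; normal = 0).
  Published tables rarely state their convention; ours is documented rather
  than asserted against any published value.
* Hedges's *g* standardizes the later-minus-earlier mean change by the
  pooled SD of the two waves' sum scores with small-sample factor
  $J = 1 - 3/(4\,\mathrm{df} - 1)$, df = pairs − 1; the paired *t* is
  reported in earlier-minus-later orientation, so deterioration gives a
  negative *t* alongside a positive *g*.
* Edge ranking breaks ties lexicographically by (from, to); zero edges are
  never listed.
* Every random stage takes an explicit seed and the pipeline manifest
  records them; a rerun with the same configuration reproduces all outputs
  byte-identically.

## Problem sizes used in the validation suite

The package's simulation studies run at the sizes a single desk CPU handles
comfortably: parameter and hub recovery use 20 replicates of n = 4000;
null-model sparsistency 10 replicates of n = 10,000; bootstrap-coverage
experiments 50 replicates of 200 bootstraps at n = 1000 (the coverage
experiment scores CIs on the generator's latent continuous values, with an
identity first-wave covariance and innovation SDs $\sqrt{1 - \sum_i B_{ji}^2}$
so every outcome has unit variance — the standardized-scale estimand is then
exactly the generating coefficient, and the check isolates bootstrap
behaviour from ordinal attenuation and scale distortion); case-drop
stability 100
subsamples per level at n = 4000. The bundled analysis scripts use a
2,000-subject, 3-wave cohort with 200 bootstraps.

## Known limitations

* Ordinal attenuation: with 3–4 categories and skewed thresholds,
  standardized edge weights are attenuated relative to the latent
  coefficients (roughly 20–30% for the skewest items). Sign recovery and
  rankings are robust to this; absolute magnitudes are conservative.
* The cross-validated `"min"` rule overselects under pure noise (a median
  ~11% of cross-lagged entries come out non-zero at n = 10,000 on a null
  process, matching `cv.glmnet`'s `lambda.min` behaviour exactly) — CV-MSE
  minimization is prediction-optimal, not model-selection consistent. The
  conservative `"1se"` rule is essentially exact under the null (≤ 5%,
  typically 0%); null-sparsistency guarantees attach to it, and the
  validation suite tests them there.
* Two-wave CLPNs cannot separate within- from between-person dynamics, and
  a 13-node network with one loneliness item inherits that item's limited
  construct coverage.
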