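---
title: "Temporal PCA and the pupillary manifold: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal PCA and the pupillary manifold: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilmanifold)
```

## The model

A phasic pupil trace is modelled as the superposition of a small number of
latent autonomic processes. Each trial $i$ on a common post-onset grid of $p$
timepoints is written

$$x_i(t) = m(t) + \sum_{k=1}^{K} s_{ik}\, v_k(t) + \varepsilon_i(t),$$

where $m$ is the grand-mean trace, $v_k$ are component loading curves and
$s_{ik}$ the per-trial scores — the trial's coordinates on the low-dimensional
manifold of trace shapes. Temporal PCA estimates $v_k$ as eigenvectors of the
trials-by-timepoints covariance: every timepoint is a variable, every trial an
observation. Because pupil samples are strongly autocorrelated, very few
components reconstruct almost all the variance, and the scores
$s_i = V^\top (x_i - m)$ are both compact and temporally informed (each score
is a loading-weighted average of the whole trial).

Plain PCA orders components by explained variance and keeps them orthogonal;
its first component simply mirrors whatever dominates the data. To separate
processes rather than variance, the rotated pipeline follows the
factor-analytic tradition: standardize columns (correlation-metric PCA),
scale eigenvectors by $\sqrt{\lambda_k}$ so loadings are
timepoint–component correlations, then apply **promax**: varimax first, an
idealized target $|\ell|^{\kappa}\mathrm{sign}(\ell)$ next, and a
least-squares oblique transformation onto that target. The resulting
components may correlate (matrix $\Phi$; structure $= $ pattern $\times \Phi$),
which is physiologically sensible — autonomic processes are not orthogonal.
Scores use the regression method, $W = R^{-1}S$ applied to standardized
columns, where $R$ is the timepoint correlation matrix and $S$ the structure
matrix.

The three processes the rotated solution targets, in ascending peak latency:
parasympathetic activation (the early light-reflex constriction),
parasympathetic inhibition, and sympathetic activation (late dilation).

## Preprocessing contract

Inputs are long-format tables (subject, trial, time in ms with 0 at target
onset, pupil, per-trial conditions), artifacts already marked as missing.
The pipeline is: linear interpolation of gaps up to `max_gap` (default
500 ms; longer or edge gaps stay missing), z-scoring per subject over the
whole session (sample SD, $n-1$), baseline subtraction of the mean in a
500-ms window centered on onset ($[-250, 250)$ ms), epoching to the
half-open interval $[0, 4500)$ ms — 450 samples at 100 Hz — and matrix
construction with the strict omission rule: any trial still containing a
missing sample is dropped whole. Epochs are half-open so sample counts are
exact; missing data are `NA`, never sentinels. The order interpolate →
z-score → baseline is the default and configurable; z-scoring per subject is
chosen because the aim of the transform is comparability across subjects.

## Inference

Three time-course tests operate per timepoint on complete trials:

* `lmem_timecourse()` — mixed model with by-subject random intercept; the
  condition effect is tested by a likelihood-ratio test on maximum-likelihood
  fits. This avoids degrees-of-freedom approximations, which differ across
  implementations. Multiplicity is handled by Benjamini–Hochberg FDR across
  timepoints by default; numeric-looking condition levels are treated as
  ordered-numeric (configurable).
* `cluster_permutation()` — family-wise control: per-timepoint within-subject
  slope t statistics, clusters formed at a two-sided `cluster_alpha`, cluster
  mass = sum of $|t|$, null distribution = maximum cluster mass over
  within-subject shuffles of trial condition labels (the exchangeable unit),
  with the add-one estimator $(1 + \#\{null \ge obs\})/(1 + n_{perm})$.
* `bf_timecourse()` — Jeffreys–Zellner–Siow Bayes factors: the standardized
  effect gets a zero-centered Cauchy prior (scale $r = \sqrt{2}/2$ by
  default), expressed as a normal mixture over $g \sim$ IG$(1/2, r^2/2)$ so
  BF$_{10}$ is a one-dimensional integral over $g$, evaluated on the
  log-$g$ scale by adaptive quadrature. Subjects enter as additive fixed
  nuisance; evidence is flagged at BF$_{10} > 3$.

The recommended path, however, is `score_model()`: one mixed model per
component score, with by-subject random intercept (random slopes opt-in,
falling back with a message when singular). Estimates and Wald intervals come
from the REML fit, p-values from the ML likelihood-ratio test.

## The synthetic generator

`simulate_pupil_data()` is the statistical twin of a passive-luminance
experiment: 20 subjects × 64 trials, 8 levels balanced within subject,
450 samples. Basis curves are gamma-family pupil-response kernels
$b_k(t) = \mathrm{pol}_k\,(t/t_{max,k})^{n} e^{n(1-t/t_{max,k})}$ with shape
$n = 10.1$, unit peak magnitude, peak latencies 900/1800/3200 ms and
polarities $(-1, +1, +1)$ — the early component constricts, and its peak
falls where the light reflex is expected (1–1.5 s) once combined with the
mean trace. The kernels overlap in time, so the generating basis is
deliberately non-orthogonal: the regime where oblique rotation is genuinely
advantaged. True scores follow
$s_k = \beta_{0k} + \beta_{1k}(x - \bar x) + u_{k,subj} + e_{k,trial}$ with
defaults $\beta_0 = (1.2, 0.6, 0.5)$, $\beta_1 = (0.12, 0.04, 0.04)$ score
units per luminance step (the constriction component carries most of the
light effect), subject SD 0.3 and trial SD 0.4 per component. Additive noise
is stationary AR(1) with $\phi = 0.95$ and innovation SD 0.03 (≈ 0.1 z-units
stationary SD): baseline-corrected, z-scored pupil traces are smooth, and
this floor reproduces the empirical regime in which roughly three components
carry some 95% of trace variance. Artifacts are single contiguous gaps of
50–400 ms inserted in 5% of trials. Random streams are partitioned by
(subject, trial), so extending the design never reshuffles existing trials.

What the generator does *not* emulate: tonic drifts beyond AR(1), blink
dynamics in the raw eye-tracker stream, uneven trial lengths, or
non-stationary noise. Tests passing on the twin therefore validate the
algebra, calibration and recovery behaviour of the pipeline — not every
property of real recordings.

One consequence worth noting: with positive luminance effects on both the
constriction and the dilation components, the per-timepoint effect crosses
zero mid-trial, so the mixed-model time course on the twin typically reports
*two* flagged clusters separated by the crossover; summaries therefore quote
the onset of the first and offset of the last flagged run.

## Numerical choices

* Eigen-decomposition via SVD of the centered matrix; eigenvalues clamped at
  0; variance shares always use the total variance of all components, so
  truncation does not change them.
* Sign convention everywhere: the element of largest absolute value in a
  loading column is made positive (signs are mathematically arbitrary; a
  deterministic rule makes runs reproducible). Rotated components are
  reordered by descending rotated variance share.
* Varimax iterates planewise SVD steps, Kaiser row normalization on by
  default, stopping at criterion gain < 1e-10 or 1,000 sweeps; promax power
  $\kappa = 4$ (the customary default of the method, which does not itself
  prescribe one). A singular promax target system falls back to varimax with
  a warning.
* Regression scoring inverts the timepoint correlation matrix; when it is
  (near-)singular — fewer trials than timepoints, or noiseless low-rank
  data — a ridge of 1e-8 is added to the diagonal and a message emitted.
* Degenerate inputs fail loudly and early: zero-variance columns (pre-onset
  samples after baseline correction) point the user to post-onset epoching;
  zero-spread z-score groups name the group; fewer than two complete trials
  abort matrix construction.

## Problem sizes in the test suite

The suite validates calibration at desk scale, chosen once: type-I error of
the per-timepoint mixed model over 500 null replicates (10 subjects × 16
trials); family-wise cluster error over 200 replicates of the generator with
the condition effect switched off (8 subjects × 16 trials, 30 timepoints,
1,000 permutations) — the autocorrelated generator null, not white noise,
because the procedure's calibration is only meaningful on the data it is
designed for; score-model coverage over 300 replicates; component recovery
over 50 seeds of the full default design. Oracles are independent routes:
`eigen(cov(X))` for the PCA, a 0.0001-rad grid search for varimax,
`stats::varimax`/`stats::promax` for rotation cross-checks, dense 3-D grid
quadrature over $(\mu, \delta, \log\sigma)$ for the Bayes factor, and
closed-form cases for the FDR step-up.

## Known limitations

* Oblique axis identification is approximate: on strongly overlapping bases
  promax recovers the generating components with congruence ≈ 0.95–0.99, not
  exactly; score correlations inherit that ceiling. The regression-scoring
  step itself is exact given the true structure (verified in the suite).
* Likelihood-ratio p-values are asymptotic; with very few subjects/trials
  the per-timepoint tests can drift from nominal level. The calibration
  tests document the regime where they hold.
* `cluster_permutation()` and `bf_timecourse()` require a numeric or
  two-level condition (the within-subject slope statistic); multi-level
  categorical designs should use `lmem_timecourse()` or `score_model()`.
* Uneven trial lengths and response-locked epochs are out of scope; the
  pipeline assumes a fixed post-onset grid.
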