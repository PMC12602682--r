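# pupilmanifold

Dimensionality reduction and time-course inference for phasic pupillometry.

## The problem

Pupil size is a single, heavily autocorrelated channel in which several
autonomic processes — an early parasympathetic constriction (the pupillary
light reflex), a later release of parasympathetic inhibition, and a slow
sympathetic dilation — are superimposed on every trial. Testing the raw trace
timepoint by timepoint multiplies comparisons and ignores that the latent
processes, not the individual samples, are the quantities of interest.

`pupilmanifold` implements the alternative: treat each trial's epoch as a
point in a timepoints-dimensional space, reduce it with **temporal PCA**
(each timepoint a variable, each trial an observation), and summarise every
trial by a handful of component **scores** — its coordinates on a
low-dimensional *pupillary manifold*. With loadings `V` (timepoints × k),
per-timepoint means `m` and a trial vector `x`, the scores are
`s = Vᵀ(x − m)` and the trial is reconstructed as `m + V s`. The
factor-analytic extension scales eigenvectors by `√λ`, applies **promax
rotation** (oblique: components may correlate, captured by the `Φ` matrix),
and estimates scores by the regression method `W = R⁻¹ S` on standardized
columns — yielding components that map onto the three autonomic processes
instead of a single variance-ordered mixture.

For inference the package offers both roads: mixed-effects or
Jeffreys–Zellner–Siow Bayes-factor tests per timepoint (with BH-FDR or
cluster-based permutation control), and the recommended "few values" path —
one mixed model per component score. A fully parameterised synthetic
generator (three gamma-family basis kernels plus AR(1) noise, known
ground-truth scores) makes the whole stack verifiable without any external
data.

## Worked example

```r
library(pupilmanifold)

# simulate the default study: 20 subjects x 64 trials, 8 luminance levels,
# 450 post-target samples at 100 Hz
sim <- simulate_pupil_data(simulation_spec(seed = 7))
rec <- interpolate_gaps(sim$recording)      # fill short artifact gaps
tm  <- to_trial_matrix(rec)                 # complete trials x timepoints

red <- temporal_pca(tm, ncomp = 3)
print(red)
#> <pupil_pca> 1279 trials, 450 timepoints, 3 component(s) retained
#>   variance shares: 60.5%, 24.2%, 12.2%  (cumulative 97.0%)

rr <- rotated_pca(tm, ncomp = 3, rotation = "promax")
print(rr)
#> <pupil_rpca> 1279 trials, 3 rotated component(s) [promax]
#>   rotated variance shares: 33.8%, 21.5%, 13.6%
#>   max |inter-component correlation|: 0.36

recovery_report(sim, rr)[, 1:4]
#>             component matched congruence   score_r
#> 1 parasymp_activation       3 -0.9824451 0.9626605
#> 2 parasymp_inhibition       2  0.9816896 0.9518187
#> 3     symp_activation       1  0.9708932 0.9879658
```

Three components reconstruct 97% of the simulated traces; after promax
rotation the explanatory power is spread more evenly and each recovered
loading curve matches its generating autonomic basis with Tucker congruence
≈ 0.97 (sign is arbitrary), with trial scores correlating ≥ 0.95 with the
generating scores. Score-level inference then reduces to one small model per
component:

```r
st <- scores_table(red, add = "luminance")
score_model(st, fixed = "luminance")   # estimate, SE, CI, LRT p per score
```

Time-course tests on the same data: `lmem_timecourse()` (per-timepoint mixed
model, BH-FDR flags, clusters), `bf_timecourse()` (JZS Bayes factors,
Cauchy prior scale √2/2), `cluster_permutation()` (family-wise control by
max-cluster-mass permutation within subjects).

A command-line wrapper over the same functions ships in
`inst/cli/pupilmanifold.R` with `simulate`, `reduce` and `test` subcommands.

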