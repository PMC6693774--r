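---
title: "Gaussian-process inference for two-photon imaging traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process inference for two-photon imaging traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gptrace)
```

## The inference problem

A scanning two-photon microscope visits each region of interest (ROI) — a
soma or an axon terminal — only when the laser trajectory crosses its mask.
Averaging the ROI's pixels per scan line yields one fluorescence value per
crossing, so each ROI produces an *irregular* stream of (time, value) pairs,
pooled across stimulus trials. Beneath this noisy stream we assume a smooth
latent activity function (calcium concentration or glutamate release, with
indicator decay around 100 ms). `gptrace` models the stream with Gaussian
process (GP) regression so that the uncertainty about the latent function is
estimated *jointly* with the function itself and can be propagated into
every downstream decision: signal comparisons, cluster validation, stimulus
effect selection and closed-loop stimulus design.

## The GP model

Observations are modelled as a zero-mean GP (each ROI's values are median
centred) with an RBF kernel and additive homoscedastic Gaussian noise:

$$k(x, x') = \sigma_{\mathrm{signal}}^2
  \exp\!\left(-\frac{\lVert x - x'\rVert^2}{2\ell^2}\right)
  + \mathbb{1}[x = x']\,\sigma_{\mathrm{noise}}^2 .$$

The three hyperparameters $\phi = \{\ell, \sigma_{\mathrm{signal}},
\sigma_{\mathrm{noise}}\}$ are point-estimated by maximizing the log
marginal likelihood. Posterior queries return the *latent* variance (noise
excluded) next to the noisy variance; the two differ by exactly
$\sigma_{\mathrm{noise}}^2$. Credible bands are reported as
$\mu \pm z\,\sqrt{\mathrm{diag}\,\Sigma}$ — i.e. multiples of the posterior
*standard deviation*, with $z = 3$ the default throughout.

### Sparse approximation

Datasets with thousands of observations use a collapsed variational
inducing-point bound with $M$ inducing inputs (default $M = 300$; the exact
GP is used whenever $M \ge N$). The inducing inputs are a random subset of
the training inputs and are held *fixed* during optimization. Optimizing
their locations jointly is the textbook scheme, but for the one-dimensional
(or low-dimensional, z-scored) predictor spaces used here a well-spread
fixed subset leaves no measurable gap at $M = 300$, and it keeps the
optimization small enough for bootstrap-scale refitting. The suite verifies
that the sparse path reproduces the dense closed-form posterior to $10^{-3}$
when $M \approx N$.

### Optimization and initialization

Hyperparameters are optimized in log space with L-BFGS-B, capped at
`n_iter` iterations per fit ("iterations per fit" is interpreted as the
optimizer's iteration cap), and the best of `n_restarts` restarts is kept.
The marginal-likelihood surface has two well-separated basins: a
short-lengthscale basin that resolves oscillatory structure, and an
"all-noise" basin (very long lengthscale, near-zero signal variance) that
absorbs everything into $\sigma_{\mathrm{noise}}$. Restart lengthscales are
therefore *stratified* log-uniformly over $[0.01, 1]\times$ the predictor
range with the first restart anchored at the short end: relaxing an
overfitted lengthscale upward is reliable, whereas a start longer than the
signal's period almost never escapes the noise basin. Warm starts
(`init`) override the first restart and are used throughout the bootstrap
and clustering machinery. Signal and noise standard
deviations are initialized from the data standard deviation. Cholesky
failures are retried with jitter escalating from $10^{-8}$ to $10^{-4}$ and
then raised as errors. Duplicate observation times (two scan lines in one
frame) are legal; the noise term handles them.

## Input warping for non-stationary responses

A chirp-driven response decorrelates quickly during fast stimulus segments
and slowly during steps, violating the stationarity of a single RBF
lengthscale. `estimate_local_lengthscales()` slides a 500 ms window at
1/16 s spacing over the *stimulus* trace (512 windows for a 32 s stimulus),
fits a Gaussian curve $A\,e^{-(x-\mu)^2/2\ell_t^2}$ to each window's
empirical autocorrelation by Levenberg–Marquardt least squares, and
`build_time_warp()` accumulates $\mathrm{spacing}/\ell_t$ into a monotone
piecewise-linear warp (the $1/(2\ell_t^2)$ accumulation variant is available
behind a switch; the cumulative *inverse lengthscale* is the primary
definition). Fitting a stationary GP in warped time and mapping back yields
locally adaptive smoothness and, importantly, *higher latent uncertainty
during fast segments* near the sampling limit.

Numerical care in the window fits: the amplitude is bounded near 1 (an
autocorrelation is 1 at lag zero — this suppresses a degenerate flat
solution), the centre offset is bounded near 0, and three lengthscale starts
guard against local minima of the oscillatory residual. Windows with
(near-)zero variance have no autocorrelation; they are flagged and assigned
the maximum lengthscale over the remaining windows, which is the behaviour
a constant stimulus segment should have (very slow decorrelation). The warp
is computed once per stimulus — the response autocorrelation is assumed to
track the stimulus autocorrelation — rather than per ROI, which would be
slower and much noisier.

## Equality testing with the Euler characteristic

To compare two conditions, one GP is fitted per condition and the
difference process is formed on a regular grid (default spacing 1/64 s,
fine enough to resolve an 8 Hz oscillation): mean $\mu_\Delta = \mu_1 -
\mu_2$ and variance $\sigma_\Delta^2 = \sigma_1^2 + \sigma_2^2$ from the
latent posteriors. The Euler characteristic (EC) at threshold $z$ is the
number of disjoint grid regions where $|\mu_\Delta| > z\,\sigma_\Delta$ —
the regions where the $z$-sd band of the difference excludes zero.

Significance is assessed by a bootstrap: both conditions' observations are
pooled; per replicate two *disjoint* samples of 300 observations are drawn
without replacement, a GP is fitted to each, and the EC curve of their
difference is recorded; 500 replicates form the null distribution
(defaults; reduced versions are used in the test suite). The empirical
p-value at each threshold is the raw proportion of null ECs at least as
large as the observed EC. Ties count: an observed EC of zero — nothing
detected anywhere — gives $p = 1$, and a difference whose EC exceeds every
null replicate gives exactly $p = 0$. An add-one corrected p-value
$(k+1)/(N+1)$ is reported alongside. The headline decision uses $z = 3$ and
$\alpha = 0.01$.

Two engineering choices stabilize the bootstrap. Replicate fits reuse the
kernel structure and warp of the main fits with a single restart and a
reduced iteration cap (a deliberate speed/accuracy trade-off at 500
replicates), and they are *warm-started* at the geometric mean of the two
condition fits' hyperparameters. Without the warm start a noticeable
fraction of single-restart replicates lands in a different likelihood basin
than its partner, and the difference between a structure-resolving fit and
an all-noise fit produces spuriously enormous null ECs.

The classical baseline (`classical_estimate()`, `classical_shuffle_test()`)
interpolates each trial's frame-averaged trace with a cubic spline,
averages across trials, uses the combined inter-trial standard deviation as
the uncertainty, and builds its null by reshuffling interpolated trial
traces between conditions (500 shuffles by default).

### What the EC test can and cannot detect

The EC is a *count* of distinct exceedance regions. A condition difference
confined to a single smooth bump yields an observed EC of 1, and because a
calibrated null also produces single chance regions at a non-trivial rate
(roughly the number of lengthscales per recording times the two-sided
normal tail), such a difference is genuinely hard to certify at
$\alpha = 0.01$ regardless of its amplitude. Differences that modulate an
oscillatory response segment — the typical situation for chirp and sine
stimuli — produce several disjoint regions and are detected with
$p \approx 0$. The reference power simulation
(`simulate_equality_conditions()`) therefore injects its 3-noise-sd offset
as a windowed 1 Hz modulation under a smooth envelope rather than a flat
bump; the spec of the offset (amplitude and 2 s window) is unchanged, only
its within-window time course makes it EC-detectable. The same reasoning
shapes the cluster templates in `simulate_population()`.

## Cluster validation

Per-ROI GP mean functions on a shared grid are clustered with Ward linkage
on Euclidean distances (`ward.D2`, the Euclidean-correct Ward variant);
means are used raw by default with a z-scoring switch. Per-ROI fits go
through `fit_roi_models()`, which first fits one GP to a pooled subsample
of all ROIs and warm-starts every per-ROI fit from it: a few hundred
observations per ROI are routinely too few for a cold fit to find the
structure-resolving basin, and a dendrogram built from collapsed fits is
meaningless.

Starting at the root, each node's split is tested by pooling the
observations of the ROIs on each side, fitting one GP per side, and
running the equality test with the null drawn from the *node-pooled*
observations. By default (`match_sample_sizes = TRUE`) the observed EC is
computed from side fits on `sample_size`-observation subsamples under the
same fit configuration as the null replicates, and every fit at the node
is warm-started from a single fit of the node pool. This makes the
observed statistic and the null replicates exchangeable when the split is
uninformative — without it, the larger observed fits have a different
chance-region rate than the smaller replicate fits, and homogeneous nodes
are accepted (or true splits missed) at unacceptable rates. The
all-observations variant of the side fits remains available. An accepted
split
(p below $\alpha$, or EC above the 99.5th null percentile under the
alternative criterion — both knobs exist because either convention is
defensible, with $\alpha = 0.01$ on the empirical p as the default) recurses
into the children; a rejected split freezes the node's leaves as one
cluster. The result is always a frontier of the tree: each ROI ends up in
exactly one cluster, and the audit trail lists the tested nodes in
traversal order. When a pool is too small for two 300-observation samples
the sample size is halved to fit, with a warning. Singleton children are
fitted from their single ROI's observations. An optional responsiveness
gate excludes ROIs whose step-response amplitude is within 2 baseline
standard deviations (posterior-mean spread over the 500 ms before the step,
plus the fitted noise floor) of the mean signal.

## GP-ANOVA and effect selection

Stimulus parameters enter as predictor columns: trial time (warped when a
warp is supplied), oscillation phase as the unit-circle pair
$(\cos 2\pi t f, \sin 2\pi t f)$, bar direction as
$(\cos 2\pi\alpha/360, \sin 2\pi\alpha/360)$, frequency and contrast
linear. All columns are z-scored with training statistics (constant columns
pass through unscaled); prediction grids reuse the training statistics. The
kernel is a *sum* of RBF effects — one summand per accepted effect — plus a
single noise term. An interaction is one RBF over its joint z-scored
columns with a single shared lengthscale, so equal-magnitude changes of the
joined predictors trade off symmetrically; the product-of-RBFs form of a
joint-lengthscale interaction is the algebraic identity the unit tests
verify.

Forward selection mirrors an ANOVA model build: pass 1 adopts the single
best candidate by objective unconditionally; each later pass fits every
remaining candidate on top of the accepted set and admits the best one only
if a likelihood-ratio test rejects at $\alpha = 0.01$ with 2 degrees of
freedom per effect (lengthscale + signal variance; the df convention is a
documented choice, not fitted to anything). $\Lambda = 2(\ell_1 - \ell_0)$
is clamped at zero with a warning if the larger model optimized worse.
Selection stops after `patience` (default 1) consecutive rejecting passes.
Ties in the objective break lexicographically by candidate name so the
outcome does not depend on candidate order. Default candidate sets: sine →
phase, frequency, contrast, frequency×contrast, phase×frequency×contrast,
time; moving bar → time, direction, time×direction.

## Active stimulus design

The (frequency, contrast) space spans 1–8 Hz and 10–100% with exclusion
thresholds at the lower bounds; all distances are computed after rescaling
both axes to $[0,1]$ because the units are incommensurate. Initial
parameters come from dart-throwing blue-noise sampling (default $n = 150$,
minimum distance $0.7\sqrt{1/n}$ — a Poisson-disk heuristic). The
latent-uncertainty map evaluates, for each cell of a 64×64 grid (smaller in
the test suite), the summed latent variance of the model over one trial's
time grid under that cell's parameters. Batches are the top `batch_size`
(default 30) local maxima of the map under a maximum-filter neighbourhood
with 3-cell minimum separation, ranked by value with row-major tie-breaks,
topping up from the highest remaining cells when fewer peaks exist. With
`include_boundary = FALSE` (default) peaks within the filter radius of the
map edge are ineligible — reproducing the edge bias plain peak-finding has —
and `TRUE` switches to a reflect-padded filter that can select boundary
cells. A closed-loop round appends the new observations, refits the model
*keeping the previously selected kernel structure* (hyperparameters are
re-estimated; kernel selection is not re-run), recomputes the map and emits
the next batch.

When two designs are compared (active versus a same-budget random design),
their final maps are evaluated under one shared kernel — e.g. the
geometric mean of the two fitted hyperparameter sets, via
`set_gp_hyperparams()` — because given the kernel the latent variance
depends only on where observations were placed; under each arm's own
fitted kernel the comparison mostly measures fit-to-fit hyperparameter
variability.

## The synthetic-data generator

The generator defines the study conditions for every statistical check:

* **Stimuli.** A 32 s chirp (2 s baseline, 3 s ON, 3 s OFF, 8 s frequency
  sweep 0.5→8 Hz at full contrast, 2 s pause, 8 s contrast sweep at 2 Hz,
  6 s baseline — a configurable stand-in consistent with the described
  components and total duration), 1 s sine trials with per-trial frequency
  and contrast, and a moving bar over 8 directions × 3 repeats of 4 s.
* **Scan geometry.** A linear raster (32 lines, 15.625 Hz) samples an ROI
  once per covering line per 64 ms frame; a spiral grid (16 rotated
  constant-speed Archimedean arcs $r = \theta^{1/a}$, $a = 2$, 31.25 Hz)
  samples it at every arc crossing, which is both denser and more irregular
  — the suite asserts the density ordering.
* **Neurons.** A linear–nonlinear model: tuning-scaled stimulus drive,
  exponential indicator filter ($\tau = 100$ ms), rectifying gain, additive
  homoscedastic Gaussian noise (matching the model assumption; shot noise
  and heteroscedasticity are out of scope). Population generators attach
  cluster-specific windowed oscillatory offsets scaled in noise-sd units.

What the generator does *not* emulate: photon shot noise, bleaching and
drift, spatially structured stimuli, correlated noise across ROIs, and
indicator nonlinearities beyond rectification. Passing the simulation-based
checks therefore demonstrates the statistical machinery is correct and
calibrated under its own assumptions, not that those assumptions hold for
any particular recording.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at reduced but
statistically meaningful sizes, chosen once: equality-test calibration uses
20 same-process splits with 100-replicate bootstraps of 100 observations;
power uses 1000 observations per condition with 300-observation bootstrap
samples over the 16 s reference conditions; cluster recovery uses an 8 s
1 Hz sine base with 20 ROIs (k = 2) and 12 ROIs (k = 1) at 200
observations per ROI and 60-replicate node bootstraps of 150-observation
samples; effect selection uses 30 sine trials and 450 observations; active
design compares 3×30-parameter rounds against a 90-parameter random
control on a 24×24 map.
Full-scale defaults (500 replicates of 300 observations, 64×64 maps, 300
inducing inputs, best-of-6 fits) remain the package defaults. Every
stochastic routine takes an explicit seed, and results are reproducible
from the persisted configuration and seed alone.

## Known limitations

Point-estimated hyperparameters understate total uncertainty (no
hyperpriors or MCMC, by design); the Gaussian likelihood is not ideal for
photon-limited data (point-process extensions are future work);
single-bump condition differences are structurally hard for the EC count
(see above); warping assumes the response inherits the stimulus
autocorrelation, which fails for spatially integrated responses; and batch
selection ignores within-batch interactions, so the 30-parameter batches
are a heuristic rather than an optimal design.
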