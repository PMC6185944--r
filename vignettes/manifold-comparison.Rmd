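---
title: "Comparing neural manifolds and latent dynamics across motor tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing neural manifolds and latent dynamics across motor tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the model

Motor cortical population activity during a single task is well described by
a low-dimensional linear manifold: most covariance across tens of recorded
units is captured by a handful of *neural modes* (principal components), and
the time courses of their activation — the *latent dynamics* — carry the
signals that matter for behavior. This package implements a complete
statistical pipeline for asking whether those modes and dynamics are
*preserved across tasks*: whether the manifolds of two tasks are similarly
oriented in neural space, whether their latent trajectories are correlated
after an optimal within-manifold alignment, how much of the latent activity
is task-independent, and whether any of this could be explained trivially by
similarity of the motor output itself.

Throughout, activity is treated linearly: the manifold of task $A$ is the
span of the leading $m$ eigenvectors $\mathbf{W}_A$ of the unit-covariance
of the smoothed, square-root-transformed firing rates
$\mathbf{X}_A \in \mathbb{R}^{n \times T}$. Nonlinear manifold estimators
are deliberately out of scope.

## Preprocessing

* Spike counts in 20 ms bins are square-root transformed (variance
  stabilization for Poisson-like counts) and convolved per unit with a
  Gaussian kernel (s.d. 50 ms, truncated at ±4 s.d. and renormalized to
  unit mass).
* Smoothing is applied *per trial*, never across trial boundaries, and the
  kernel is additionally renormalized by the mass falling inside the trial.
  The second point matters more than it looks: plain zero-padded
  convolution attenuates the first and last ~100 ms of every trial by the
  same factor in every unit, which plants a spurious, perfectly
  condition-independent "time" component in the data. That artifact
  inflates manifold similarity and contaminates the time marginalization of
  dPCA; edge renormalization removes it at no cost to interior bins.
* Raw EMG becomes an envelope by 4th-order zero-phase Butterworth high-pass
  at 10 Hz, rectification, 4th-order zero-phase low-pass at 50 Hz, then
  division by the channel's 99th percentile pooled over the whole session.
  Zero-phase filtering uses odd reflect-padding of 3× the filter order.
  The raw sampling rate is never assumed; it must be given (the generator
  uses 1000 Hz).
* Trial averaging truncates every trial to the shortest successful trial
  and discards unsuccessful trials.

## Manifold orientation

Principal angles between two bases come from the SVD
$\mathbf{W}_A^\top \mathbf{W}_B = \mathbf{P}_A \mathbf{C} \mathbf{P}_B^\top$,
with singular values clamped to $[0, 1]$ before the arccosine; angles are
reported in degrees, ascending. Significance is assessed against surrogate
data generated by a tensor maximum-entropy model: the maximum-entropy
Gaussian over the trial-averaged tensor whose expected marginal covariances
over *time* and over *targets* equal the data's, while the neuron marginal
is constrained only to an isotropic target (total variance / n), so that
covariance across neurons — the quantity under test — is destroyed. The
solution has Kronecker-structured eigenvectors and eigenvalues
$1/(\lambda^T_i + \lambda^N_j + \lambda^C_k)$; the multipliers are fitted by
BFGS on the convex dual, with rank-deficient marginals floored at $10^{-9}$
of the largest eigenvalue. Each surrogate pair is pushed through the same
pipeline (concatenate conditions, PCA, principal angles), and the per-rank
threshold is the 0.1th percentile (empirical order statistic, linear
interpolation) of the surrogate angle distribution. Surrogates are compared
surrogate-vs-surrogate, matching the wording of the method this implements;
a fast "neuron-shuffle" fallback (independent permutation of unit
identities) is provided and agrees with the maximum-entropy thresholds
within 20% in the test suite.

The across- to within-task VAF ratio uses the reconstruction-error VAF and a
chance ceiling from Haar-uniform random manifolds (QR of a Gaussian matrix
with sign-corrected R diagonal). The source text for this control describes
the chance bound once as the "0.1th" percentile of the random-manifold VAF
distribution and elsewhere as the 99.9th; a *maximum expected by chance* is
the upper tail, so the 99.9th percentile is implemented.

## Latent comparison (CCA)

Latent matrices for a task pair are built from trial- and target-equalized
windows: $k$ = the minimum successful trial count over all conditions of the
pair, a fixed window per trial starting at target onset (default 700 ms;
clamped with a warning if trials are shorter), trials ordered by a common
target sequence. 2-D center-out targets are matched to 1-D targets by the
sign of their horizontal projection. CCA is computed by QR of the transposed
latent matrices and SVD of $\mathbf{Q}_A^\top \mathbf{Q}_B$, with transforms
$\mathbf{M}_i = \mathbf{R}_i^{-1}\mathbf{U}$ (resp. $\mathbf{V}$).
Correlations are clamped to $[0,1]$; rank-deficient inputs are refused
rather than regularized.

Two references bracket the observed correlations: a within-task ceiling
(split-half, target-matched, full pipeline per half, 100 repetitions, 99.9th
percentile per rank; odd condition counts drop one trial) and a bootstrap
null (joint time permutation of one side, re-smoothed with the 50 ms kernel
to restore autocorrelation, 5000 draws at full scale, 99.9th percentile).
The window offset relative to target onset is configurable and defaults to
zero.

## Demixed PCA

The trial-averaged tensor (mean-subtracted per neuron) is decomposed into
time, task, target, and task/target marginalizations — the classic balanced
factorial decomposition, which reconstructs the centered tensor exactly and
is pairwise uncorrelated. Per marginalization the least-squares map
$\mathbf{A}_\phi = \bar{\mathbf{X}}_\phi \bar{\mathbf{X}}^\top
(\bar{\mathbf{X}}\bar{\mathbf{X}}^\top)^{-1}$ is rank-reduced through the
SVD of $\mathbf{A}_\phi \bar{\mathbf{X}}$; candidate modes are pooled across
marginalizations, ranked by VAF, and the top $m$ kept, each labeled by its
marginalization. No regularization is applied by default (the analytic
solution); a trace-scaled ridge is available for singular cases and its use
is logged. Decoders are orthonormal within a marginalization but not across
modes, so VAF always uses the explicit reconstruction form. Balanced designs
are required; unbalanced designs are rejected rather than reweighted.

## EMG decoding and the EMG-driven null model

Decoders are Wiener cascades: a multi-input linear filter over lags
0…M−1 into the past (M defaults to 10 bins = 200 ms, a typical history
length for cortex-to-EMG decoding at 20 ms bins; the source does not state
a value) solved by least squares, followed by a static second-order
polynomial. Cross-validation is leave-one-fold-out over contiguous 30 s
folds; reported values are the fold-mean R² and its ratio to an all-modes
decoder ("normalized R²"). Decoding inputs are dPCA mode activations:
encoders estimated on trial-averaged data, applied to single-trial rates
(the alternative — projecting onto concatenated-trial PCA axes — is also
supported).

The null model simulates each unit as Poisson with rate
$\lambda_j(t) = a_j + \sum_i b_{ji}\,\varepsilon_i(t) + \eta_j(t)$,
$a_j \sim U[0, 0.1]$, $b_{ji} \sim U[-1, 1]$, Gaussian noise of variance
0.05, rectified at zero (a Poisson mean must be nonnegative) and then scaled
multiplicatively per unit to match target mean rates. One subtlety: the
rectification is a nonlinearity that can expand the rank of the *unsmoothed*
rate matrix; the low-dimensionality of the simulation should be (and in the
tests is) assessed on the smoothed rates, where the simulated population
concentrates its variance within roughly the number of EMG channels.

# The synthetic-session generator

Real recordings of this kind are not publicly archived, so the generator is
a first-class module and defines the study conditions used by all tests:

* 60 units, 2 tasks × 3 targets × 12 successful trials, 40-bin (800 ms)
  trials with ±10% length jitter; baseline 0.3 events/bin (~15 Hz, typical
  of multi-unit threshold crossings); 12 planted modes (4 time, 4 target,
  2 task, 2 task/target) with latent s.d. 4 (pre-nonlinearity); 6 EMG
  channels at 1000 Hz with envelope signal-to-noise 10.
* Rates are `softplus(b0 + W L)` per bin (positive without clipping
  artifacts), with `b0` the softplus inverse of the baseline; a linear
  link clipped at zero is available for parity with the purely linear null
  model and is the right regime for mode-recovery tests, where the
  measurement chain should be as close to linear as possible.
* Each planted mode's trajectory varies *only* with its labeled parameter:
  time modes are identical across conditions, target modes are centered
  across targets, task modes across tasks, interaction modes
  double-centered. Within a class the trajectories are
  Gram–Schmidt-orthogonalized: smooth random curves at trial length are
  mutually correlated by chance, and without orthogonalization only the
  planted *subspace*, not individual modes, is identifiable. For the same
  reason, mode-recovery tests plant distinct per-mode amplitudes
  (`latent_sd` accepts a vector); with equal variances the demixing is
  rotation-degenerate within a marginalization.
* Task-specific manifolds (`shared_subspace = FALSE`) are planar rotations
  of selected loading columns into the population orthogonal complement, so
  the planted principal angles are known analytically.
* EMG envelopes are a mixing of the (unit-variance-normalized) target
  latents plus a per-muscle baseline and task offset, with additive Gaussian
  noise at `snr_emg` and rectification; the raw trace is a white-noise
  carrier amplitude-modulated by that envelope, which exercises the full
  filter-rectify-filter chain.

What the generator does *not* emulate: refractoriness or spike-history
effects, non-Poisson count dispersion, electrode crosstalk or unit drift,
behavioral kinematics, and nonlinear (curved) manifolds. Passing tests
therefore demonstrate that the pipeline recovers planted linear structure
under Poisson observation noise at realistic rates and session lengths — not
that real cortical data satisfy those assumptions.

# Numerical choices and degenerate inputs

* Eigenvector and mode signs follow a fixed convention (largest-magnitude
  element positive) for reproducibility.
* Principal-angle cosines and canonical correlations are clamped to
  $[0, 1]$ before arccos/reporting.
* Quantiles are empirical order statistics (type-7 linear interpolation);
  ensembles too small to resolve the requested quantile raise an error
  rather than extrapolate.
* Zero-variance inputs: PCA refuses degenerate data; all-zero EMG channels
  are flagged and left unnormalized; zero-rate simulated units are permitted
  and logged.
* Monte Carlo sizes default to desk scale (1000 surrogates, 500–1000
  bootstraps) with the full-scale values (10,000 / 5000) one flag away
  (`analysis_config(full_scale = TRUE)`). The acceptance script uses 1000
  surrogate pairs, 10-seed replications, and 100 unit-dropping pairs; the
  test suite uses the same sizes where a distributional claim is made and
  smaller ones for plumbing checks.
* All stochastic stages take explicit seeds; the pipeline derives per-stage
  seeds from one master seed, so any stage can be reproduced in isolation.

# Known limitations

* The TME fit constrains *expected* marginal covariances; individual
  surrogates fluctuate around the targets (the tests bound the ensemble
  mean within 10% relative Frobenius error).
* The trailing principal angles of an m-dimensional comparison are
  intrinsically noisy: even for a genuinely shared subspace the weakest
  modes sit near the noise floor, so the significant-angle count rarely
  reaches m exactly.
* CCA windows assume a fixed trial-aligned epoch; no time warping is
  attempted.
* dPCA requires balanced, target-equalized designs; sessions that cannot be
  equalized should use the CCA route instead.
* Wiener-cascade decoding is intentionally simple (no state-space or
  recurrent decoders), matching its role as a comparative probe of mode
  subsets rather than a performance-maximizing decoder.
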