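# neuromodes

Tools for asking whether a motor cortical population reuses the same
low-dimensional *neural manifold* — and the same latent dynamics within it —
across different motor tasks, or instead recruits its neurons in
task-specific combinations.

The package is written for systems neuroscientists working with chronic
multielectrode recordings from motor cortex (binned multi-unit spike counts,
trial metadata, and multichannel EMG), and for anyone who wants a tested,
self-contained implementation of the underlying subspace statistics.

## What it computes

For each task, population activity is summarized by an *m*-dimensional PCA
manifold: the span of the leading *m* principal components (neural modes) of
the smoothed, square-root-transformed firing rates **X** (n units × T bins).
The package then compares tasks along four complementary axes:

- **Manifold orientation.** The principal angles θ₁ ≤ … ≤ θ_m between two
  manifolds come from the SVD of the basis inner product,
  `t(W_A) W_B = P_A C t(P_B)`, with `C = diag(cos θᵢ)`. Observed angles are
  judged against tensor-maximum-entropy (TME) surrogates: maximum-entropy
  Gaussian datasets whose expected covariance over time and across targets
  matches the data while covariance across neurons is destroyed. Angles below
  the 0.1th percentile of the surrogate distribution are "significantly
  small". A second orientation statistic is the across- to within-task VAF
  ratio, `VAF(X_A → W_B) / VAF(X_A → W_A)`, with a chance ceiling from
  10,000 randomly oriented manifolds.
- **Latent dynamics.** Canonical correlation analysis (QR of the transposed
  latent matrices, SVD of `t(Q_A) Q_B`) aligns the two tasks' latent
  trajectories and returns correlations rank by rank, bounded above by a
  within-task split-half ceiling and below by a time-permutation bootstrap
  null.
- **Task-independent structure.** Demixed PCA factorizes the trial-averaged
  tensor into time-, target-, task-, and task/target-related
  marginalizations and fits reduced-rank per-parameter readouts, so that
  each kept mode carries a behavioral label and a variance share. VAF under
  any encoder/decoder pair uses the reconstruction form
  `VAF_h = (‖X‖² − ‖X − D_h E_h X‖²)/‖X‖²`, including the non-orthogonal
  decoder correction `D_h = W M_h (t(M_h) M_h)⁻¹` for CCA directions.
- **Relation to muscle output.** Wiener-cascade decoders (lagged linear
  filter + static quadratic nonlinearity) predict EMG envelopes from small
  subsets of dPCA modes, cross-validated on contiguous 30 s folds and
  normalized by an all-modes decoder. An EMG-driven Poisson null model
  (`λⱼ(t) = aⱼ + Σᵢ bⱼᵢ εᵢ(t) + ηⱼ(t)`) asks whether manifold and latent
  similarity across tasks could follow from motor-output similarity alone.

Because equivalent public recordings are not available, the package ships a
first-class synthetic-session generator that plants known loadings, labeled
latent trajectories, and EMG mixing, so every stage is validated end to end
against ground truth.

## Worked example

```r
library(neuromodes)

gs <- generate_session(synthetic_config(seed = 1))
session <- gs$session
session
#> <neural_session>
#>   60 units x 2888 bins (20 ms bins), 72 trials
#>   tasks: 1, 2; targets: 1, 2, 3
#>   EMG: 6 channels at 1000 Hz

cfg <- analysis_config(n_surrogates = 1000, n_boot = 1000, seed = 1,
                       fold_seconds = 10)
report <- run_full_analysis(session, cfg)
report
#> <session_report> 2 task(s); stages: angles, vaf, cca, dpca, decoding
#>   angles 1-2: k = 9 of 12 significantly small
#>   VAF ratio 1-2: 0.60 / 0.58 (chance 0.32)
#>   CCA 1-2: leading CC 0.98, 12 above null
#>   dPCA total VAF 92.7%
#>   decoding (target): mean normalized R2 0.81
#>   decoding (time): mean normalized R2 -0.05
#>   decoding (task): mean normalized R2 -0.08
#>   decoding (task_target): mean normalized R2 -0.30
```

Reading the report: this session was generated with a *shared* 12-mode
subspace, and the analysis recovers that — 9 of the 12 principal angles
between the two task manifolds are below the TME surrogate threshold; the
across-task VAF ratio (~0.6 in each direction) is far above its
random-manifold chance level (0.32); all 12 canonical correlations of the
latent dynamics exceed the bootstrap null (leading CC 0.98); and EMG is
decoded essentially as well from the two leading target-related dPCA modes
as from all 12 modes (normalized R² ≈ 0.8), while time-, task-, and
interaction-related modes carry no EMG information. A session generated
with `shared_subspace = FALSE, rotation_angle = 90` instead yields 0
significantly small angles.

Individual stages are available as ordinary functions (`fit_pca`,
`principal_angles`, `tme_surrogates`, `cca`, `fit_dpca`, `crossval_r2`,
`simulate_population`, `unit_dropping_control`, ...); see the methods
vignette (`vignettes/manifold-comparison.Rmd`) for the model, parameter
choices, and caveats.

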