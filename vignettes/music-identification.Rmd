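---
title: "Identifying musical pieces from auditory-cortex fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying musical pieces from auditory-cortex fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`musid` implements a two-stage voxel-wise encoding / stimulus-identification
pipeline for naturalistic music fMRI, together with the synthetic-data
generator that makes every stage testable without scanner data. This
vignette explains the model, the parameters that matter, the numerical and
design choices we made where the methodology was genuinely open, and what
the synthetic experiments do and do not establish.

## The experimental layout

A `stimulus_design()` describes the temporal structure everything else
relies on: `n_pieces` musical pieces of `piece_duration_s` seconds (defaults
40 × 46 s), concatenated into `n_medleys` medleys of `pieces_per_medley`
pieces (4 × 10), each medley presented once per run and each run repeated
over `n_sessions` scanning sessions (4). At `tr_s = 2` s a piece spans 23
volumes and a run is 245 volumes: 10 warm-up volumes, 230 stimulus volumes,
and a 5-volume tail that absorbs the hemodynamic delay of the last piece.

Three index conventions are fixed once, in `piece_volume_window()`, and used
everywhere:

* **Hemodynamic delay.** A piece's BOLD window is the piece's nominal volume
  range shifted rigidly forward by `hemodynamic_delay_vols` (3 volumes,
  6 s). The shift is applied to the *BOLD* window, not to the feature
  window; lagging the features instead would be an equivalent
  parameterization, and the shift size is configurable.
* **Transition trimming.** Pieces are cross-faded in the medleys, so the
  first and last `transition_trim_vols` (3) volumes of the *shifted* window
  are dropped for identification, leaving 17 of 23 volumes
  (shift-then-trim). Training uses the full 23-volume windows; trimming
  only protects the decoding comparison from fade contamination.
* **Indexing.** All windows are 1-based inclusive ranges within a run, the
  natural convention in R.

Cross-validation folds (`enumerate_folds()`) are exhaustive for 2 or 3 test
pieces (780 and 9,880 folds over 40 pieces) and uniformly sampled without
replacement — via lexicographic-rank unranking, so sampling is exactly
uniform over the `choose(n, k)` subsets — for larger test sets, 10,000 by
default, under a single recorded seed. `medley_folds()` holds out a complete
run (10 pieces) at a time.

## Feature conditioning

The 21 musical features (9 timbral descriptors, 10 sub-band flux
coefficients, pulse clarity, key clarity; see `musical_feature_names()`)
enter the model after a fixed conditioning chain, in this order:

1. **HRF convolution** (`hrf_kernel()`): a double-gamma kernel — difference
   of two gamma densities, peak-normalized — with a 5-s peak delay
   (auditory responses peak slightly earlier than the 6 s conventional for
   visual cortex), 16-s undershoot delay, 1-s dispersions and a 1/6
   undershoot ratio. Published auditory-HRF parameter sets vary and the
   exact values are not critical for identification (all pieces pass
   through the same kernel), so every parameter is exposed in `hrf_spec()`
   and the defaults are documented as a configurable stand-in.
2. **Downsampling** to the TR by decimation (every 160th sample for
   12.5-ms audio frames), keeping phase 0 (sample indices 1, 161, …); the
   phase is configurable because decimation phase is a free choice.
3. **Savitzky–Golay detrending** with the same filter used for the BOLD
   data (below).
4. **Joint normalization** (`normalize_joint()`): each feature is
   standardized over the concatenation of all medleys, not per medley, so
   level differences between medleys remain informative signal. Variances
   use the population denominator *n* throughout the package, keeping
   normalization and correlation computations on one convention.

## BOLD preprocessing

`preprocess_run()` applies, per run and in this order: Savitzky–Golay
detrending, nuisance regression, global-signal correction, temporal
Gaussian smoothing, and per-voxel z-normalization.

* The Savitzky–Golay filter uses a 242-s window and polynomial order 3; the
  window in samples, `round(242 / tr_s)`, is forced odd (121 at TR = 2 s)
  because the filter requires odd windows. Edge samples use the filter's
  standard polynomial-fit edge behaviour. An order-3 filter reproduces
  cubic drift exactly in the window interior, which is why the synthetic
  generator uses cubic per-run drift: detrending must remove it almost
  perfectly, and a test asserts ≥ 0.99 correlation between preprocessed
  drifted and drift-free data at zero noise.
* Nuisance regression (`regress_out()`) accepts any volumes × k regressor
  matrix (in the scanner setting, 21 physiological confounds built from
  cardiac/respiratory phase expansions and response functions; their
  construction is out of scope here). Rank-deficient regressor sets are
  handled by pivoted QR with a warning.
* "Global-signal correction" is ambiguous in common usage; both readings
  are implemented — regressing out the across-voxel mean (default) and
  subtracting it directly.
* The 5-s temporal Gaussian "width" is read as FWHM (σ = 5/2.355 s),
  truncated at ±4σ and renormalized near the edges so constants pass
  through; the width is configurable because the convention is ambiguous.
* Whether global-signal correction precedes or follows nuisance regression
  is not determined by the methodology; we fix nuisance → global → smooth.

## Encoding and voxel ranking

`fit_encoding()` runs an independent OLS per voxel of BOLD on an intercept
plus the conditioned features, aggregating the full windows of all training
pieces over all sessions (4 × 38 × 23 = 3,496 rows for pairwise folds;
repeated presentations contribute their own rows and are *not* averaged for
training — averaging happens only on the decoding side). With 3,496 rows
against 21 parameters, regularization is unnecessary, and the package
deliberately implements none.

`rank_voxels()` estimates each voxel's predictability by an inner five-fold
cross-validation *within the training pieces only*: the training pieces are
split into five contiguous blocks at piece boundaries (so no piece
straddles folds and autocorrelation cannot leak across the inner split),
the model is refit on each complement, and predicted/measured correlations
are averaged over folds. With 38 training pieces the blocks hold 8 or 7
pieces (736 or 644 rows) rather than an exact 80/20 row split — the
piece-blocked partition is the safer reading. Ranking is descending by
score with ties broken by ascending voxel id; a leakage test asserts that
mutating test-piece data changes neither weights nor ranking.

## Identification

`identify_pair()` restricts measured and predicted blocks to the top
`n_voxels` ranked voxels and first `n_timepoints` trimmed volumes,
concatenates each space × time block to a single vector, and compares
Pearson correlations. Choices fixed here:

* Measured blocks are averaged over the four presentations *after*
  preprocessing, before identification.
* Blocks are concatenated and then correlated (not z-scored per dimension
  first) — the literal reading of the procedure.
* Correlation ties, and degenerate zero-variance vectors (possible at 1
  voxel × 1 time point), count **against** the decoder and are flagged.
* The sweep's default voxel grid is {2, 5, 10, 25, 50, 100, 200, 300, 500,
  1000}; the time sweep always starts at the first trimmed volume and
  grows contiguously.

`identify_nway()` generalizes to N candidates: predictions are ranked by
correlation, the true piece must rank first to count as correct, ties give
it the worst tied rank (conservative), and ranked accuracy is
`(N − rank)/(N − 1)`. `permutation_null()` permutes piece labels at the
decoding stage only (encoding fits untouched), which for pairs reduces to
an independent fair label swap per fold; because the two outcomes of a fold
share one swap — and folds share pieces — the null is wider than a
binomial, which a test verifies against the binomial quantile oracle.

## Shannon entropy of a piece

`entropy_table()` computes, over the entire stimulus set, the Pearson
correlation between the 21-feature vectors at every pair of distinct time
points; the global range of these similarities is split into 10 equal bins,
and each piece's entropy is `−Σ p_i log2 p_i` over the histogram of its
within-piece pair similarities (`0 log 0 = 0`), bounded by `log2 10 ≈ 3.32`
bits. Conventions: bins are left-closed/right-open with the last bin closed
(so the maximum similarity is counted); self-pairs are excluded; full
23-volume windows are used by default (`trimmed = FALSE` exposed);
similarities are computed on the conditioned features, since the feature
space the model sees is the conditioned one. A piece whose feature
trajectory barely moves has all similarities in one bin and entropy 0.

## Feature topography

`feature_correlations()` computes *univariate* temporal correlations
between each feature and each of the top-300 ranked voxels — deliberately
not a joint regression, so collinear features cannot bias each other's
apparent topography. `feature_pca()` takes principal components of this
voxels × 21 map with features as variables: mean-centered, not re-scaled
(correlations already share a scale), with a deterministic sign convention
(largest-magnitude loading positive). Component counts are configurable
(default k = 4; formal component-count tests such as parallel analysis are
out of scope). `component_similarity()` uses |r| between loadings because a
component's sign is arbitrary, and `stable_match()` runs Gale–Shapley with
the individual's components proposing, preferences by descending |loading
correlation|, ties broken by component index — the proposer-optimal stable
matching, verified in tests against exhaustive enumeration of all
matchings.

## Sparsity sweep

`sparsity_sweep()` reruns encoding + pairwise identification with the first
m = 1…21 features, twice — ascending and descending variance inflation
factor (`vif_order()`, VIF = 1/(1−R²), infinite for exact collinearity) —
and averages the two curves, so the arbitrary ordering of correlated
features neither flatters nor penalizes small models. Accuracy is taken at
100 voxels and the full 17-volume window. `fit_accuracy_curve()` compares a
saturating exponential `a(1 − e^{−bm}) + c` with a logarithmic `a ln m + b`
by residual sum of squares; the exact functional forms are not dictated by
the methodology, so these canonical three- and two-parameter families are
our choice, with range-based initialization (`a = max−min`, `c = min`,
`b = 0.2`) and a grid restart on non-convergence. Within one VIF order the
training R² is non-decreasing in m by OLS nesting; identification accuracy
need not be monotone and is not asserted to be.

## The synthetic-data generator

`synthetic_config()` + `simulate_dataset()` emulate the full experimental
layout with known ground truth:

* **Features**: per piece, a constant mean feature profile (`piece_mean_sd`,
  default 1 — pieces differ in average timbre) plus AR(1) dynamics
  (`feature_ar_coeff`, default 0.5) with compound-symmetry cross-feature
  covariance (correlation 0.3 — musical features are correlated), scaled by
  a per-piece `piece_gain` (default 1).
* **BOLD**: voxel series are the conditioned features times a ground-truth
  weight matrix, placed at the hemodynamically delayed windows, plus
  per-run cubic drift and AR(1) Gaussian noise (marginal sd `noise_sd`,
  default 0.5; lag-1 correlation 0.3). 100 of 150 voxels are responsive by
  default, mirroring a limited music-responsive pool; weights are
  N(0, 1/21), giving responsive voxels signal sd ≈ 1 so `noise_sd` is
  interpretable as 1/SNR. Each session gets independent noise and drift.
* Everything is reproducible from one seed, via isolated RNG streams that
  do not disturb the caller's random state.

The generator reproduces the *structure* of the experiment — piece/medley
layout, repeated presentations, autocorrelated noise, slow drift,
correlated features — but not spatial smoothness of voxel noise,
physiological noise structure, inter-subject variability, or any real
acoustic content; passing tests therefore establish correctness of the
pipeline's computations and its qualitative behaviour (accuracy growing
with time points, saturating over voxels, collapsing to chance under label
permutation), not empirical claims about brains.

**The entropy ensemble.** To probe the information-content account — pieces
with richer feature dynamics should be easier to identify — we give half
the pieces a small dynamics gain (0.15) and half a large one (2). Low-gain
pieces cling to their mean feature profile: their time-point similarities
concentrate near 1 (low entropy) and they offer almost no temporal signal,
only a spatial pattern; high-gain pieces spread their similarities over the
bins (high entropy) and carry strong temporal signal. The ensemble's noise
level (sd 10) was set when the ensemble was designed so that binary
accuracy sits below ceiling: at the generator's default noise this
generator is identified perfectly regardless of gain, while at far higher
noise the temporal signal drowns entirely and the contrast disappears.
Tests average the high/low-entropy accuracy split over 20 replicate
datasets.

## Problem sizes and determinism

The test suite and the acceptance script run the full 40-piece, 4-session
design wherever a claim depends on scale (3,496 training rows, 780 pairs,
the 45-pair entropy subsets), with modest voxel counts (12–120) and
subsampled fold sets (20–120 pairs) for the identification sweeps; property
suites use smaller designs (8–20 pieces, 2 sessions) chosen to keep the
whole suite in the low minutes on one CPU. These sizes are the package's
own choices and are stated in the tests. All stages are deterministic
given their seeds; `run_full_analysis()` threads one master seed through
every stage and writes byte-identical outputs on repeated runs.

## Known limitations

* Audio feature extraction itself is out of scope: synthetic features stand
  in, honoring the 21-feature schema.
* Head-motion realignment, physiological regressor construction, anatomical
  masks and surface visualization are out of scope; nuisance regression is
  a generic contract.
* The auditory HRF parameters are a documented configurable stand-in, not a
  fitted estimate.
* Group-level statistics on accuracies (permutation ANOVAs, lateralization
  tests) are not implemented; the package stops at the per-dataset
  quantities those tests would consume.
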