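---
title: "Streaming tensor regression with recursive exponentially weighted N-way PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming tensor regression with recursive exponentially weighted N-way PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Adaptive neural decoders — for instance a brain–computer interface mapping
electrocorticographic (ECoG) or magnetoencephalographic (MEG) activity to limb
trajectories — must be (re)calibrated from data that arrive continuously, in
small batches, on a device that cannot store or refit the full history. The
natural predictor for such signals is a tensor: each analysis epoch is a
frequency × time × channel slab of wavelet power, and the response may itself
be multiway (e.g. 3-D coordinates of several joints). `rewnpls` implements a
streaming estimator for the multilinear regression

$$\hat{\underline{Y}} = \underline{X} \, \underline{B}, $$

where $\underline{X} \in \mathbb{R}^{N\times I_1\times\dots\times I_n}$,
$\underline{Y} \in \mathbb{R}^{N\times J_1\times\dots\times J_m}$ share the
observation mode, and $\underline{B}$ is a coefficient tensor over all input
and output modes.

## The model and the recursion

The estimator is N-way partial least squares (NPLS) rewritten so that the data
enter only through cross-product statistics. After each incoming batch
$(\underline{X}_t, \underline{Y}_t)$ of $L$ epochs the package updates, with a
forgetting factor $\lambda \in [0,1]$:

* the effective epoch count $N^{\mathrm{eff}} \leftarrow \lambda
  N^{\mathrm{eff}} + L$ and, per tensor coordinate, the exponentially weighted
  sum $S$ and sum of squares $SS$ of both blocks, from which the effective
  mean $\mu = S/N^{\mathrm{eff}}$ and standard deviation
  $\sigma = \sqrt{(SS - S^2/N^{\mathrm{eff}})/(N^{\mathrm{eff}}-1)}$ follow;
* the raw covariance accumulators
  $\Sigma_{XX} \leftarrow \lambda\,\Sigma_{XX} + X_t^\top X_t$ and
  $\Sigma_{XY} \leftarrow \lambda\,\Sigma_{XY} + X_t^\top Y_t$ on the
  vectorized (matricized) epochs.

The centered, scaled covariances that define the model are derived
analytically whenever a model is needed:

$$C_{XX} = \frac{\Sigma_{XX} - S_X S_X^\top / N^{\mathrm{eff}}}
  {\sigma_X \sigma_X^\top},\qquad
  C_{XY} = \frac{\Sigma_{XY} - S_X S_Y^\top / N^{\mathrm{eff}}}
  {\sigma_X \sigma_Y^\top}.$$

This recentring is *exact*: at $\lambda = 1$ the derived $C_{XX}$, $C_{XY}$
equal the cross-products of the pooled, pooled-moment-standardized data for
any partition of the epochs into batches, which is also asserted by the test
suite. Standardizing each batch at ingest with the moments known at that time
would make the accumulators depend on the batch partition; carrying the raw
sums and recentring on demand avoids that approximation altogether.

Factor extraction is a covariance-only kernel recursion. For
$f = 1,\dots,F_{\max}$:

1. reshape the current (deflated) $C_{XY}$ into its $(n+m)$-mode tensor form
   and compute its best rank-one approximation by alternating least squares
   (ALS); the input-mode vectors $w_f^1,\dots,w_f^n$ give the projector
   $w_f = \mathrm{vec}(w_f^1 \circ \dots \circ w_f^n)$;
2. $r_f = w_f - \sum_{j<f} (p_j^\top w_f)\, r_j$;
3. $tt_f = r_f^\top C_{XX} r_f$ (degenerate directions truncate the stack);
4. $p_f = C_{XX} r_f / tt_f$, $q_f = C_{XY}^\top r_f / tt_f$;
5. deflate $C_{XY} \leftarrow C_{XY} - tt_f\, p_f q_f^\top$;
6. $B^f = B^{f-1} + r_f q_f^\top$.

All intermediate models $B^1,\dots,B^{F_{\max}}$ are retained — this is what
makes online hyper-parameter selection cheap. For vector-valued inputs
($n = m = 1$) the recursion reproduces classical PLS2 coefficients exactly
(the suite checks agreement with an independent NIPALS implementation to
within $10^{-6}$ relative at every factor count).

Prediction applies the de-normalized model to raw data,

$$\hat{\underline{Y}} = \underline{X}\,\tilde{\underline{B}} + \underline{Y}_0,
  \qquad \tilde{B} = B\,\sigma_Y/\sigma_X,\quad
  Y_0 = \mu_Y - \mu_X \tilde{B},$$

which is algebraically identical (and tested to $10^{-10}$) to
standardize–apply–destandardize.

## Online selection of the number of factors

The only structural hyper-parameter of the PLS family is the factor count
$F$. Recursive validation selects it on the fly: every new batch is first
used as a *test* set for all intermediate models of the previous update, and
only then folded into the estimator. Per-factor errors accumulate with their
own forgetting factor $\gamma$:

$$e^f \leftarrow \gamma\, e^f + \mathrm{ERROR}(\hat{Y}^f_t, Y_t),\qquad
  F^*_t = \arg\min_f e^f,$$

with ties broken toward fewer factors. The ordering contract (score before
update) is enforced by an update counter shared between the two state
objects; calling them out of order is an error, not a silent bias.

`ERROR` is the mean squared error over epochs and output coordinates;
a normalized variant (per-coordinate squared error divided by the running
response variance, making the accumulators invariant to the response scale)
is selectable. The error accumulators start at zero, so with $\gamma = 1$
they are plain cumulative sums; no warm-up period is imposed, but
`select_model()` flags a cold start and falls back to the one-factor model
until the first batch has been scored.

Two properties of this selector deserve emphasis, because they shape what
tests can honestly assert:

* On an *exactly noiseless* stream ($Y = XB$ with no observation noise),
  every additional factor is a genuine improvement — the data contain
  nothing but the true model, the ordinary-least-squares limit is exact, and
  the accumulated validation error is monotone decreasing in $f$. The argmin
  is then $F_{\max}$, not the generating tensor rank. Identifying a
  parsimonious rank is a property of *noisy* streams, where factors beyond
  the true rank chase covariance sampling noise and generalize worse.
* Under noise the error minimum sits at or somewhat above the generating
  rank (the bias–variance trade-off is flat near the optimum), so assertions
  are made on reaching the true rank's complexity, not on exact equality at
  a particular batch.

## Design choices

**Vectorization convention.** Within any index group the first listed mode
varies fastest — R's native column-major layout — so matricized and tensor
views are the same memory and every module shares one convention.

**ALS initialization and determinism.** Cold starts use the leading singular
vector of each single-mode unfolding; iteration stops when the relative
objective change falls below `tol` (default $10^{-9}$ for the standalone
primitive, $10^{-10}$ inside factor extraction) or after `max_iter` sweeps.
The objective is non-decreasing by construction. Sign indeterminacy is fixed
after convergence (first nonzero entry of each input-side vector
nonnegative, scale nonnegative).

By default extraction does **not** warm-start from the previous update's
projectors, and this is deliberate. A streaming model is "completely
identified by the covariance matrices" only if extraction is a pure function
of them; rank-one ALS landscapes have multiple attractors, and a warm start
can settle a factor on a different stationary point than the cold start,
making the fitted model depend on the batch history rather than on the
accumulated statistics (we observed order-$10^{-2}$ prediction differences
between batch partitions of identical data when it does). With cold-start
extraction, partition invariance at $\lambda = 1$ holds to machine
precision. For latency-critical use `use_warm_start = TRUE` enables a
dual-candidate scheme — ALS from the cold start *and* from the previous
projectors, keeping the better objective — which preserves the accelerated
re-convergence idea at the cost of that strict invariance.

**Degeneracy guards.** A factor is abandoned when $tt_f$ falls below
$10^{-12}\,\mathrm{tr}(C_{XX})$ (scale-free) or when the deflated $C_{XY}$
is exactly zero; later models alias the last valid one, and prediction
beyond the valid count warns and clamps. Zero-variance coordinates are
guarded by $\varepsilon = 10^{-12}$ wherever a standard deviation divides.
Response standardization (`scale_y`) is on by default and configurable.

**Moment/covariance update order.** Moments and covariance accumulators are
updated together from the same raw batch; because recentring is analytic, no
ordering approximation arises.

## Feature extraction

`epoch_features()` maps a channels × samples recording to epoch tensors of
shape frequency × time-bin × channel. The continuous wavelet transform uses a
complex Morlet wavelet of constant Q (width 7 cycles by default, the common
neurophysiology choice), implemented as frequency-domain Gaussian band-passes
with unit peak gain, zero padding against circular wrap-around, and an
`edge_samples` attribute flagging the contaminated margins. Epochs of 1 s are
taken every 100 ms and the power modulus is averaged in 10 contiguous,
non-overlapping 100 ms bins — ten bins of equal size is the only reading of
"decimate 1000 points to 10 over one second" consistent with the counts, and
binning conserves the epoch mean exactly. The presets `ecog_config()`
(10–150 Hz in 10 Hz steps: 15 × 10 × channels) and `meg_config()` (5–100 Hz
in 5 Hz steps: 20 × 10 × channels) reproduce the standard decoder
geometries. Supervised responses should be aligned to each epoch's *end*
time (causal decoding); `epoch_features()` reports epoch start indices for
that purpose. Artifact rejection, re-referencing and line-noise filtering
are out of scope.

## Model inspection

`modality_influence()` summarizes a coefficient tensor along one mode as the
sum of absolute coefficients over all other modes, normalized to unit sum so
profiles are comparable across batches and models. For a rank-one tensor the
profile over mode $k$ is exactly $|w^k|/\|w^k\|_1$; profiles are invariant to
overall scale and equivariant under coordinate permutation. Averaging across
recordings or output coordinates is left to the caller.

## The synthetic stream generator

`stream_spec()`/`make_truth()`/`gen_batches()` generate ground-truth
streaming regressions: $B$ is a sum of `rank` rank-one outer products of
unit-norm Gaussian factors; inputs are i.i.d. standard normal; noise is
Gaussian with per-output-coordinate variance $\mathrm{Var(signal)}/snr$
(exact, since the signal variance is a column sum of squares of $B$). Drift
is modeled as a hard replacement of $B$ at a given batch (`switch`) or a
continuous rotation between two tensors. Defaults mirror an adaptive-decoder
protocol: 100-epoch batches, 70 batches per run.

The generator is deliberately *not* a biophysical model: inputs are Gaussian
rather than wavelet-textured, coordinates are uncorrelated, noise is
homoscedastic, and drift is simple. Passing tests therefore demonstrate the
estimator's statistical correctness (covariance bookkeeping, factor
extraction, rank tracking, forgetting), not decoding performance on real
neural recordings, whose spatial correlation, nonstationarity and artifacts
are outside what this generator emulates. For integration tests a
"cwt-like" route exists: sinusoid mixtures passed through `epoch_features()`
feed the estimator with realistically structured tensors.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` exercise the estimator at
deliberately modest geometries — input tensors of 120–480 coordinates
(e.g. $8\times6\times10$), 100-epoch batches, 20–70 batches, 5–10 seeds per
property — chosen so the full validation completes in a few minutes while
keeping every effect it measures (partition invariance, rank tracking,
recovery error below 10 %, forgetting benefit) far from its decision
threshold. The full ECoG-scale geometry ($15\times10\times64$, covariance
side 9600) is exercised for feature-extraction shapes; fitting at that scale
works identically but is a memory-bound exercise (a 9600² covariance is
~0.7 GB) that adds nothing to the properties under test.

## Known limitations

* Covariance storage is $O(I^2)$ in the vectorized input size; very large
  montages need dimensionality reduction upstream.
* The estimator assumes complete batches; missing data handling is out of
  scope.
* Recursive validation shares one $F_{\max}$ across the stream; it selects
  among, but does not grow, the model stack.
* The rank-one ALS solves a non-convex problem; the deterministic cold start
  makes results reproducible but, like all such schemes, cannot guarantee
  the global optimum for every covariance tensor.
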