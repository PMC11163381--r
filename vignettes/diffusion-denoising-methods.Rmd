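---
title: "Methods: diffusion denoising of Hi-C contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion denoising of Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hicdiffuse)
```

## The problem

Single-cell Hi-C assays measure chromatin contacts in one nucleus, producing
per-chromosome contact matrices that are extremely sparse and noisy compared
with bulk (population) Hi-C. `hicdiffuse` denoises such matrices with
denoising diffusion probabilistic models (DDPMs): a forward Markov chain
gradually corrupts a clean map `y0` with Gaussian noise, and a learned
reverse chain removes noise step by step. Two training regimes are
supported:

* **unsupervised / unconditional** — the noise predictor sees only the
  latent `y_t` and the step `t`; training needs clean maps only;
* **supervised / conditional** — the predictor additionally receives a fixed
  corrupted observation `x` of the same map, channel-concatenated with
  `y_t`, which doubles the first convolution's input channels.

## The diffusion model

The forward process uses a variance schedule `beta_t`, `t = 1..T`, with
`alpha_t = 1 - beta_t` and `abar_t = prod_{s<=t} alpha_s`. Its closed-form
marginal is

    y_t = sqrt(abar_t) * y0 + sqrt(1 - abar_t) * eps,  eps ~ N(0, I),

implemented by `forward_sample()`. Two schedule shapes are provided
(`make_schedule()`): `linear` (evenly spaced beta) and `sigmoid` (a logistic
ramp over logits in [-6, 6], flat at both ends). Defaults are the classic
DDPM bounds `beta in [1e-4, 0.02]`, `T = 1000`; the package's scaled
experiments use `T = 50`, which keeps the matched-start reverse chain (below)
around seven steps at noise level 0.1.

The noise predictor `f(y_t, t[, x])` is trained to minimize
`||eps - f(y_t, t[, x])||^2` with `t ~ Uniform{1..T}` (`loss_unsupervised()`,
`loss_supervised()`). The reverse step uses the standard DDPM posterior mean

    mu = (y_t - (beta_t / sqrt(1 - abar_t)) * eps_hat) / sqrt(alpha_t),

which is the parameterization consistent with that training objective.

**Reverse-step variance.** The method this package follows states the
reverse standard deviation as `sigma_t = sqrt(1 - abar_t)` evaluated at the
previous step; that is the package default (`variance =
"sqrt_one_minus_abar"`, with `abar_0 := 1` so the final step is exactly
noiseless). This choice is unusually large compared with the conventional
DDPM posterior `beta_t (1 - abar_{t-1}) / (1 - abar_t)`; because the
intended variant is genuinely ambiguous, both are implemented
(`variance = "beta_tilde"`) and neither is silently corrected. With
deterministic (mean-path) inference the two coincide.

## Denoising an observation: matched-start inference

The observation model is `x = y0 + Z`, `Z ~ N(0, sigma_x^2 I)`, applied on
the `[-1, 1]` model scale. Scaling `x` by `sqrt(abar_t)` gives
`sqrt(abar_t) y0 + sqrt(abar_t) sigma_x Z`, which matches the forward
marginal exactly when `sqrt((1 - abar_t) / abar_t) = sigma_x`.
`match_start_time()` returns the smallest such `t`, and `denoise_map()`
starts the reverse chain from the scaled observation at that step. This is
the identity-degradation special case of diffusion restoration with a known
linear corruption operator, reconstructed here because only the general
recipe — not the exact per-step listing — was available; it applies to both
modes (the conditional predictor still receives `x` at every step). A full
chain from `y_T ~ N(0, I)` is available for conditional predictors
(`start_from = "noise"`). If `sigma_x` exceeds the terminal noise-to-signal
ratio of the schedule the chain starts at `T`, with a warning.

Whole matrices are processed as 64x64 tiles with bottom/right zero padding
(`tile_map()`/`assemble_tiles()`, an exact inverse pair), then renormalized
to `[0, 1]` by `(y + 1) / 2` with clipping — the scale on which all metrics
are computed.

## Preprocessing

Raw counts are normalized per matrix by clipping at the 0.999 quantile of
the nonzero entries and dividing by the clip value (`normalize_unit()`);
`clip_quantile = 1` recovers plain max-division. Quantile clipping is the
standard Hi-C enhancement preprocessing: a single extreme entry otherwise
compresses the whole dynamic range. The `[0, 1]` map is then rescaled by
`2u - 1` (`to_model_range()`). Noise level `sigma_x` is defined on the
model scale, so `sigma_x = 0.1` corresponds to standard deviation 0.05 on
the unit scale — worth keeping in mind when reading PSNR numbers.

## Backbones

Both predictors share one contract: input tile(s) plus an integer step
(and `x` in conditional mode), output a same-shape noise estimate.

* **Residual network** (`build_residual_predictor()`, the default): a 3x3
  convolution head, `n_blocks` residual blocks (3x3 conv, additive
  per-channel time bias, ReLU, 3x3 conv, identity skip), a global skip from
  head to tail, and a 3x3 tail back to one channel — the EDSR
  super-resolution lineage. Full scale is 32 blocks / 64 channels; the
  scaled experiments use 4 blocks / 32 channels (about 87k parameters).
* **U-Net** (`build_unet_predictor()`): encoder–decoder with 2x2
  average-pool downsampling, nearest-neighbour upsampling, concatenated
  skip connections, SiLU residual blocks, and multi-head self-attention at
  the bottleneck by default.

The time step enters through a sinusoidal embedding (width 64 by default)
and a shared SiLU perceptron; each block projects the shared vector to a
per-channel bias. The tail convolution is zero-initialized, so an untrained
predictor outputs zero — the first reverse step then reduces to the
identity and early training sees well-scaled gradients. Time-embedding
width, nonlinearities (ReLU in the residual net, SiLU in the U-Net) and the
hidden widths are package choices; the published architecture reports its
total parameter count but not the hyper-parameters needed to reproduce it
exactly, so parameter counts here are not meant to match it.

## Training

`fit_predictor()` runs minibatch Adam (learning rate `1e-3` and batch size 8
by default; the scaled benchmark uses batch size 4 and learning rate `2e-3`,
picked on validation loss — small batches buy more optimization steps within
a fixed epoch budget), evaluates a validation criterion after every
epoch on a held-out split with a fixed evaluation seed (so epochs are
comparable), and returns the argmin checkpoint. The criterion is the
denoising objective on the validation tiles by default; a PSNR criterion
(deterministic matched-start denoising of the held-out noisy tiles) is
selectable. "Trained until converged" is interpreted as a fixed epoch
budget plus best-validation selection. Divergence (non-finite loss) aborts
with a diagnostic rather than returning a broken model. The whole fit is
bit-reproducible given `config$seed`.

## The synthetic generator

`generate_map()` emulates the structure the method relies on: contact
intensity proportional to `(1 + d)^-1` with genomic distance `d` (the
classic Hi-C decay), multiplicative enrichment (default 4x) inside planted
TAD blocks, Poisson counts at a set read depth mirrored to an exactly
symmetric matrix, and binomial thinning (default keep fraction 0.05) for
single-cell sparsity. The scaled benchmark uses 64-bin maps with TAD
boundaries at bins 21 and 42 and read depth 8000 before thinning, giving
roughly 90% empty entries — a realistic per-tile sparsity for single-cell
data at 40 kb resolution.

What the generator does **not** emulate: restriction-fragment and
mappability biases, A/B compartment checkerboards, loops/stripes,
chromosome-length heterogeneity, and the correlated (non-Gaussian) noise of
real experiments. Passing tests therefore demonstrate that the machinery —
schedules, samplers, objectives, backbones, metrics — behaves exactly as
specified on data with the assumed statistical structure, not that any
particular biological result will transfer to a given real data set.

## Numerical choices

* The 3x3 convolution forward/backward runs in compiled code as nine
  row-shifted single-precision GEMMs on a padded pixel-major layout. Single
  precision is a deliberate choice for the convolution arithmetic only
  (everything else is double): activations live in `[-1, 1]` and gradients
  feed Adam, so float32 changes nothing at the scale of the optimization
  while being several times faster on one CPU. Analytic gradients agree
  with finite differences to ~1e-3 relative (the float limit) and with a
  double-precision reference convolution to ~1e-6.
* All randomness flows through R's RNG; `corrupt()`, `forward_sample()`,
  `reverse_denoise()` and `fit_predictor()` take explicit seeds and restore
  the caller's RNG state.
* Degenerate inputs have defined behaviour: an all-zero matrix normalizes
  to zeros with divisor 1; identical matrices give `Inf` PSNR/SNR sentinels
  rather than errors; HiCRep strata with zero variance are skipped, and an
  all-degenerate comparison returns `NA` with a warning; insulation
  log-ratios use a `1e-9` pseudo-count.
* `sigma_x = 0` corruption returns the input object unchanged, and
  single-cell thinning with keep fraction 1 skips the thinning draw so it
  is bit-identical to bulk generation.

## Scaled problem sizes

The package's end-to-end experiment (`run_denoising_benchmark()`, also run
by `scripts/acceptance.R`) trains on 200 synthetic 64x64 single-cell tiles
corrupted at noise level 0.1, with 30 validation and 40 held-out test
tiles, `T = 50`, 30 epochs, both training modes. These sizes were chosen so
the whole experiment — data generation, two trainings, tiled inference and
the six-metric evaluation — completes in minutes on a single CPU while
still being large enough for the denoised-vs-noisy comparison to be stable
across seeds. Unit tests use smaller fixtures (tiles of 16–100 bins).

## Known limitations

* No accelerated (DDIM-style) samplers, learned variances, or
  classifier-free guidance; the reverse chain takes every step.
* Cooler/HDF5 containers are not read directly; matrices move through
  dense text, COO pixel tables (TSV) and MatrixMarket files.
* Intra-chromosomal maps only; no ICE/balancing normalization (inputs are
  assumed already normalized or raw counts).
* The unsupervised mode assumes additive Gaussian observation noise with a
  known (or estimated) level; symmetric noise fields are supported for
  corruption, but the matched-start derivation treats entries as
  independent.
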