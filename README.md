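# hicdiffuse

Denoising diffusion models for single-cell and bulk Hi-C contact maps, in R.

Single-cell Hi-C (scHi-C) measures chromatin contacts in one nucleus; the
resulting per-chromosome contact matrices are orders of magnitude sparser and
noisier than bulk Hi-C, which hampers downstream analyses such as TAD
calling. `hicdiffuse` removes additive Gaussian noise from contact matrices
with denoising diffusion probabilistic models (DDPMs), in two regimes:

* **unsupervised (unconditional)** — trained on clean maps only; a noisy
  observation is aligned to the forward trajectory and denoised by the
  reverse chain from the matched step;
* **supervised (conditional)** — trained on paired (clean, noisy) tiles; the
  observation is channel-concatenated with the latent at every step, doubling
  the first convolution's input channels.

## The model

The forward process corrupts a clean map `y0` (scaled to `[-1, 1]` by
`y = 2u - 1`) through a variance schedule `β_t`, `t = 1..T` (linear or
sigmoid), with closed-form marginal

    y_t = sqrt(ᾱ_t) y0 + sqrt(1 - ᾱ_t) ε,   ᾱ_t = Π_{s≤t} (1 - β_s),  ε ~ N(0, I).

A noise predictor `f_θ(y_t, t[, x])` — a deep residual network (default) or a
U-Net with multi-head attention — is trained to minimize
`‖ε - f_θ(y_t, t[, x])‖²`. The reverse chain iterates

    y_{t-1} = (y_t - (β_t / sqrt(1 - ᾱ_t)) ε̂) / sqrt(α_t) + σ_t z,

with `σ_t = sqrt(1 - ᾱ_{t-1})` (the conventional posterior variance is
selectable) and `σ = 0` at the final step. For denoising an observation
`x = y0 + Z`, `Z ~ N(0, σ_x² I)`, the chain starts at the smallest `t` with
`sqrt((1 - ᾱ_t)/ᾱ_t) ≥ σ_x` from the scaled observation `sqrt(ᾱ_t) x`.
Whole chromosomes are processed as zero-padded 64×64 tiles and reassembled.
Denoised maps are scored against clean references on the renormalized
`[0, 1]` scale with PSNR, SSIM, MSE, SNR, the HiCRep stratum-adjusted
correlation (SCC), and the L2 dissimilarity of TAD insulation-score vectors.

A synthetic scHi-C generator (power-law distance decay, planted TAD blocks,
Poisson counts, binomial thinning to single-cell sparsity) makes every part
of the pipeline testable without downloads.

## Worked example

```r
library(hicdiffuse)

# 1. simulate a sparse single-cell chromosome and corrupt it
params <- synthetic_params(n_bins = 256, mode = "single_cell", seed = 1)
clean  <- generate_map(params)
y0     <- to_model_range(normalize_unit(clean))
noisy  <- corrupt(y0, corruption_spec(sigma_x = 0.1, seed = 2))

# 2. train the tiny residual backbone on clean tiles (unsupervised mode)
tiles <- crop_training_pairs(y0, noisy, tile_size = 64)
sched <- make_schedule("linear", T = 50)
pred  <- build_residual_predictor(channels = 32, n_blocks = 4, seed = 3)
fit   <- fit_predictor(pred, tiles, sched,
                       train_config("unsupervised", epochs = 30, seed = 4))

# 3. denoise the corrupted map and score it
den <- denoise_map(noisy, fit, sigma_x = 0.1, seed = 5)
evaluate_maps(from_model_range(y0), den, space = "unit")
```

The end-to-end scaled experiment is packaged as one call:

```r
res <- run_denoising_benchmark(seed = 1)
res$metrics
```

which trains both modes on 200 synthetic 64×64 single-cell tiles
(σ_x = 0.1, 4 residual blocks, 32 channels, T = 50, 30 epochs) and scores 40
held-out tiles. With seed 1 it prints:

```
  condition     psnr   ssim       mse   snr hicrep insulation_l2
  noisy_input  28.53 0.5171 0.0014049  6.47 0.9398         1.599
  supervised   32.19 0.8747 0.0006084 15.43 0.9580         0.824
  unsupervised 31.93 0.8877 0.0006475 14.69 0.9506         0.958
```

Both diffusion modes improve every metric over the noisy input — PSNR by
more than 3 dB, MSE cut to less than half, SSIM from ~0.52 to ~0.88, SNR
more than doubled, HiCRep SCC and TAD insulation fidelity both up —
mirroring the qualitative behaviour of full-scale diffusion denoising of
single-cell Hi-C data.

## Command line

A thin dispatcher wraps the same functions:

```sh
exec/hicdiffuse simulate --out data/ --n-bins 256 --mode single_cell --seed 7
exec/hicdiffuse train    --data data/ --checkpoint model.rds --mode unsupervised
exec/hicdiffuse denoise  --input data/noisy_1_sigma0.1.txt --checkpoint model.rds \
                         --output denoised.txt --reference data/clean_model_1.txt
exec/hicdiffuse evaluate --reference a.txt --estimate b.txt --space model
```

Configuration is YAML plus dotted-key overrides
(`--set diffusion.T=100,noise.sigma=0.5`); every run serializes its resolved
configuration for provenance.

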