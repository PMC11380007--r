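# dpoa

Dynamic pelican optimization with image preprocessing and
imbalance-aware loss utilities.

`dpoa` is an R toolkit for a gastric-endoscopy-style image
classification workflow built around a derivative-free optimizer. It
provides, as independently usable pieces:

* **POA / DPOA** — the pelican optimization algorithm: a population of
  candidate solutions alternates a prey-directed *exploration* move,
  `k + u (p − I k)` towards a randomly sampled prey `p` that improves
  on the member's fitness (and `k + u (k − p)` away from one that does
  not), with a multiplicative *exploitation* move
  `k + R (1 − t/T)(2u − 1) k`, both under strict greedy acceptance.
  The **D**ynamic variant decays the exploration intensity
  `I_i = I_max · exp(−α i / T)` over the run. Benchmark registry and a
  mean/sd multi-run harness included.
* **Preprocessing** — non-local means denoising
  (`w(i,j) = exp(−‖P(i)−P(j)‖² / 2h²)` patch weights, compiled inner
  loop) and CLAHE (clip-redistributed tile histograms blended
  bilinearly).
* **Augmentation** — stochastic affine transforms (rotation ±100°,
  shear ±0.04, translation ±60 px, per-axis scale 0.6–5, random
  reflections) with exact inverse-mapped warping.
* **Imbalance-aware losses** — cross-entropy, weighted cross-entropy,
  focal loss, and *dynamic* per-iteration class weights
  `w_j = α(Mr_j) / Σ α(Mr_i)` driven by per-class error ratios
  `Mr = 1 − recall`.
* **Metrics** — specificity, sensitivity, accuracy, precision, MCC, F1
  (percent scale), one-vs-rest + macro for multiclass; separable
  convolution cost formulas.
* **Synthetic data** — tissue-like images with class-dependent lesions
  (classes NT/TA/MA/PA), noise models, and imbalanced 4-class feature
  tasks (default 895:1292:1495:608) with stratified 80/20 splits.
* **`tune_demo()`** — DPOA tuning a linear softmax classifier under
  the dynamic-weight loss, end to end.

## Worked example

```r
library(dpoa)

# 1. DPOA on a 2-D sphere, the published comparison protocol
cfg <- dpoa_config(population_size = 40, max_iterations = 120)
row <- run_experiment("sphere", cfg, runs = 20, base_seed = 1,
                      dimension = 2, bounds = c(-1, 1))
row
#> <DPOA on sphere: AVG 1.872e-06, STD 1.801e-06 over 20 runs x 120 iterations>
row$ledger$run_iterations
#> [1] 2400
```

The mean best objective over 20 runs is ~2e-06 — a comparison table
printing two decimals shows it as 0.00 — and the ledger confirms the
20 × 120 = 2400 run-iteration protocol arithmetic.

```r
# 2. denoise a synthetic noisy tissue image
clean <- generate_image(image_spec(64, 64, "MA"), seed = 3)
noisy <- add_noise(clean, "gaussian", level = 0.08, seed = 4)
den   <- nlm_denoise(noisy, nlm_params(5, 11, 0.3))
c(noisy = psnr(noisy, clean), denoised = psnr(den, clean))
#>    noisy denoised
#> 22.13598 34.16995
```

Denoising lifts PSNR by ~12 dB on σ = 0.08 noise.

```r
# 3. metrics from a confusion matrix
classification_metrics(confusion_counts(tp = 9, fp = 2, tn = 8, fn = 1))
#> specificity sensitivity    accuracy   precision         mcc          f1
#>    80.00000    90.00000    85.00000    81.81818    70.35265    85.71429

# 4. DPOA-tuned linear classifier on an imbalanced separable task
td <- tune_demo(n_samples = 800, n_features = 8, separation = 3, seed = 1)
td$accuracy        # held-out test accuracy, %
td$report$macro    # macro-averaged six-metric report
```

A command-line wrapper over the same functions is installed at
`inst/cli/dpoa.R` (subcommands `generate`, `denoise`, `enhance`,
`augment`, `benchmark`, `tune-demo`, `metrics`).

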