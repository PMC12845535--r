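# harpool

Pooling operators, histogram encodings, and noise-robustness benchmarks for
human activity recognition (HAR) from tri-axial accelerometer streams.

HAR systems classify short windows of pocket-worn smartphone accelerometer
data (x, y, z at a nominal 20 Hz) into activities — Walking, Jogging,
Sitting, Standing, Upstairs, Downstairs. Such data is highly redundant in
time and noisy in practice, and the choice of *pooling operator* inside a
CNN decides how much signal structure survives downsampling. `harpool` is a
toolkit for studying exactly that. It provides:

- **Two bounded pooling reducers.** For a window $X$ with extrema $M, m$,
  range $r = M - m$, and population standard deviation $\sigma(X)$:
  - *Extrema contrast pooling* (ECP):
    $\mathrm{ECP}(X) = \tfrac{M+m}{2} - \alpha r^2$ with $\alpha = 1/2$ —
    midpoint of the extrema, penalized by the squared range; sensitive to
    sharp transitions.
  - *Center minus variation* (CMV):
    $\mathrm{CMV}(X) = \tfrac{M+m}{2} - \sigma(X)$ — variation-suppressed
    midpoint; robust to noise-driven fluctuations.

  On input normalized to $[0, 1]$ both outputs are guaranteed to stay in
  $[0, 1]$ ($\sigma$ is the population form, bounded by $1/2$; the maximal
  ECP subtraction with $\alpha = 1/2$ is $1/2$). Classical max and average
  pooling are included for comparison, as scalar reducers, strided 1D/2D
  transforms, and drop-in CNN pooling layers.
- **A histogram-to-RGB encoder** turning a normalized 3×L window into a
  3-channel image (per-axis 100-bin histograms mapped to R/G/B on a 10×10
  grid) — an order-free, redundancy-discarding representation for a 2D CNN.
- **Reference 1D and 2D CNN classifiers** with pluggable pooling layers,
  implemented natively in R (BLAS-based im2col convolutions, hand-derived
  pooling gradients, Adam, class-weighted cross-entropy), following the
  reference protocol: 32/64 filters, kernels 5/3 (1D) or 3×3 (2D),
  pooling size 2, FC 128, lr 0.001, batch 64, 10 epochs.
- **A seeded noise suite**: Gaussian, salt-and-pepper, speckle, their
  mixture, deterministic displacement drift
  ($x + \alpha t + \beta\sin 2\pi f t$, $f = 0.5$ Hz), and motion-artifact
  bursts (~0.5 g).
- **A signal-deviation benchmark** comparing pooled clean vs. pooled noisy
  signals via MD, STD difference, MSE, and $1-\rho$, plus STFT
  spectrograms.
- **A synthetic WISDM-format generator** (six activities, harmonic gait
  model, exact `user, activity, timestamp, x, y, z` CSV dialect including
  the trailing-semicolon quirk) so the whole stack runs without downloads.

See the vignette `vignettes/redundancy-aware-pooling.Rmd` for the methods,
design decisions, and known limitations.

## Worked example

Simulate two users, segment into 100-sample windows with stride 50, train
the 1D CNN with ECP pooling, and evaluate:

```r
library(harpool)

rec <- generate_stream(config = generator_config(n_users = 2,
                                                 seconds_per_activity = 60,
                                                 seed = 42))
w <- segment_windows(rec, window_len = 100, stride = 50)
w
#> <har_windows> 286 windows of length 100 (2 user(s))
#>    Walking    Jogging    Sitting   Standing   Upstairs Downstairs
#>         48         48         47         48         48         47

sp <- split_windows(w, seed = 42)                 # stratified 70/15/15
norm <- fit_minmax(sp$train)                      # fit on train only
train_w <- apply_minmax(sp$train, norm)
test_w  <- apply_minmax(sp$test, norm)            # clipped to [0, 1]

model <- build_cnn_1d(100, pooling = pooling_spec("ecp", 2), seed = 42)
model <- train_cnn(model, train_w,
                   weights = class_weights(train_w$label),
                   config = train_config(epochs = 10, seed = 42))
classification_report(test_w$label, predict(model, test_w),
                      predict(model, test_w, type = "prob"))
#> <har_report> accuracy = 1
#>       class precision recall f1 f2 f0.5 auc support
#>  Downstairs         1      1  1  1    1   1       7
#>     Jogging         1      1  1  1    1   1       7
#>     ...
```

The synthetic classes are deliberately well-separated, so a clean run
reaches perfect held-out accuracy at this scale; the interesting behavior
appears under noise. The deviation benchmark on walking windows (20
windows × 5 seeds here) reproduces the characteristic ordering — max
pooling loses the most correlation, average the least, ECP in between:

```r
walking <- synthetic_normalized_windows(20, seed = 1, activities = "Walking")
benchmark_poolings(walking,
  profiles = list(gaussian = noise_profile("gaussian", sigma = 0.2),
                  salt_pepper = noise_profile("salt_pepper", amount = 0.2)),
  seeds = 1:5)
#>    noise_type pooling     md   std   mse one_minus_rho n_undefined_rho
#> 1    gaussian     max 0.0798 0.086 0.033          0.52               0
#> 2    gaussian average 0.0143 0.071 0.019          0.46               0
#> 3    gaussian     ecp 0.0375 0.080 0.024          0.49               0
#> 4    gaussian     cmv 0.0789 0.088 0.033          0.54               0
#> 5 salt_pepper     max 0.0789 0.117 0.048          0.63               0
#> 6 salt_pepper average 0.0068 0.085 0.026          0.58               0
#> 7 salt_pepper     ecp 0.0475 0.102 0.035          0.61               0
#> 8 salt_pepper     cmv 0.0747 0.113 0.044          0.64               0
```

Scalar reducers are available directly: `ecp(c(0, 1))` is `0` (maximum
contrast), `cmv(c(0.2, 0.4, 0.6))` is `0.23670`.

A thin command-line wrapper ships in `inst/scripts/harpool`
(`simulate`, `pool-bench`, `train-eval` subcommands).

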