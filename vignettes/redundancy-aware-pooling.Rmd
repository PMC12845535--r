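---
title: "Redundancy-aware pooling for accelerometer activity recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundancy-aware pooling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(harpool)
```

## The problem

Human activity recognition (HAR) from a pocket-worn smartphone reduces to
classifying short windows of tri-axial accelerometer data (x, y, z at a
nominal 20 Hz) into activities such as Walking, Jogging, Sitting, Standing,
Upstairs, and Downstairs. Two properties of such data shape this package:

* **High temporal redundancy.** At 20 Hz, consecutive samples of a steady
  activity are highly correlated; summaries of a window often carry as much
  class information as the ordered samples.
* **Noise.** Real streams carry impulsive spikes, smooth sensor drift,
  multiplicative transmission artifacts, and bursts from device handling.

`harpool` implements a method stack built around these observations: two
bounded pooling operators, a histogram-to-image window encoding, reference
1D/2D CNN classifiers with pluggable pooling, a seeded noise-injection
suite, and a signal-level robustness benchmark, all exercisable on a
synthetic generator that emulates the WISDM CSV recording format
(`user, activity, timestamp, x, y, z`).

## The pooling operators

For a window $X$ with $M = \max(X)$, $m = \min(X)$, range $r = M - m$ and
population standard deviation $\sigma(X)$:

* **Extrema contrast pooling (ECP):**
  $\mathrm{ECP}(X) = \frac{M + m}{2} - \alpha\, r^2$, with $\alpha = 1/2$
  by default. The midpoint of the extrema is penalized by the squared
  range, emphasizing sharp local transitions.
* **Center minus variation (CMV):**
  $\mathrm{CMV}(X) = \frac{M + m}{2} - \sigma(X)$. Subtracting the
  intra-window variation suppresses noise-driven fluctuations, a
  deterministic variance-aware alternative to mean smoothing.

Both operators are **bounded on normalized input**: if every value lies in
$[0, 1]$ then the midpoint lies in $[0, 1]$, $r^2 \le 1$, and
$\sigma \le 1/2$, so with $\alpha = 1/2$ both outputs stay in $[0, 1]$.
Two consequences drive implementation decisions:

* $\sigma$ **must be the population form** (divide by $n$). The sample
  standard deviation of $\{0, 1\}$ is $\approx 0.707 > 1/2$ and would break
  the bound; the population form attains exactly $1/2$ there.
* $\alpha = 1/2$ is the largest coefficient that preserves the bound (the
  maximum possible subtraction is then $1/2$, attained at maximum contrast:
  $\mathrm{ECP}(\{0,1\}) = 0$). Smaller values are exposed via
  `pooling_spec(alpha =)` for ablation only; `alpha` is restricted to
  $(0, 1/2]$.

Useful identities, all covered by tests: a flat window pools to its
constant value under all four methods (max, average, ECP, CMV); for
two-element windows $\mathrm{CMV}(X) = \min(X)$ exactly; both reducers
commute with constant shifts and depend only on the multiset of values.

Min–max normalization to $[0, 1]$ is therefore a **precondition**, not a
convenience. `fit_minmax()` fits global per-axis extrema on the training
split; `apply_minmax()` applies them with clipping, so held-out data always
satisfies the precondition while inter-window amplitude differences are
preserved. Per-window normalization would also satisfy the bound but
destroys amplitude cues that separate, e.g., walking from jogging; it was
rejected as the default for that reason. The signal-level functions accept
a `strict` flag that rejects out-of-range input outright. Inside the CNNs,
activations after ReLU are *not* range-guaranteed; the pooling layers apply
the formulas as-is without clamping, matching how such networks are
trained in practice without inter-layer re-normalization.

## Pooling as CNN layers

`pool_1d()`/`pool_2d()` apply a reducer over strided windows (length
$\lfloor (L - s)/t \rfloor + 1$; trailing partial windows dropped). The CNN
layers use the identical vectorized reducers, so layer outputs are
bit-identical to the signal-level transforms — a tested invariant.

Since no deep-learning framework is available to R in this stack, the
reference networks are implemented in vectorized base R: convolutions as
BLAS matrix products via an im2col/col2im scheme, pooling layers with
hand-derived backward passes, Adam, and class-weighted cross-entropy.
Subgradient choices at the non-differentiable points: gradients flow to the
*first* occurrence of the window maximum and minimum (as in mainstream
frameworks' max pooling); for CMV the variation term's gradient
$(x_i - \bar{x})/(n\sigma)$ is defined as 0 on flat windows ($\sigma = 0$).
All gradients are verified against central finite differences in the test
suite (layer-level and full-model, both architectures, all four pooling
methods).

Architectures follow the reference protocol: the 1D path takes 3×100 raw
windows through two conv blocks (32 and 64 filters, kernels 5 and 3,
stride 1, 'same' zero padding, ReLU, pooling size 2 stride 2), a 128-unit
FC layer and softmax over six classes (flatten width 64·25 = 1600); the 2D
path takes 3×10×10 histogram images through 3×3 convolutions and 2×2
pooling (10 → 5 → 2, flatten 64·4 = 256). 'Same' padding is a documented
choice (the protocol states kernels and strides but not padding); it keeps
the flatten arithmetic simple. No dropout or batch normalization is used,
and weight initialization is He-scaled normal keyed to the run seed.
Training: Adam, learning rate 0.001, batch 64, 10 epochs, cross-entropy
with optional inverse-frequency class weights
($w_c = N/(K n_c)$, from `class_weights()`).

## Histogram-to-RGB encoding

`encode_rgb()` discretizes each axis of a normalized window into 100
uniform bins over $[0, 1]$ (half-open bins, last bin closed), normalizes
counts by the window length and rescales each channel by its maximum, then
reshapes the 100 counts **row-major into a 10×10 grid** per axis, stacking
x→R, y→G, z→B. The result deliberately discards sample order: shuffling a
window in time leaves its image unchanged. That is the redundancy-reduction
idea at the representation level, and it is asserted as a test invariant.

The 2D arrangement of a bin vector is not canonical; the row-major square
grid was chosen so that 3×3 convolutions see genuinely two-dimensional
neighborhoods while adjacent bins stay adjacent along rows. Alternative
shapes (and bin counts 50/200) are configurable via `encoder_config()`.
Anyone comparing pixel-level outputs against other implementations should
treat the grid shape as a free parameter. PNG export is 8-bit quantized and
for inspection only; training always consumes the exact arrays.

## Noise models

The injectors operate on normalized signals and are fully seeded
(bit-identical output for a given seed):

* `add_gaussian(sigma = 0.2)` — i.i.d. additive $N(0, \sigma^2)$; the
  pre-clip noise array is attached for calibration.
* `add_salt_pepper(amount = 0.2)` — each position independently corrupted
  with probability `amount` (replaced count ~ Binomial), exactly half of
  the corrupted positions set to 1 and half to 0.
* `add_speckle(variance = 0.2)` — multiplicative $x + x n$,
  $n \sim N(0, \mathrm{var})$; for a constant signal $c$ the pre-clip
  output sd is $c\sqrt{\mathrm{var}}$ in closed form.
* `add_mixture()` — gaussian → salt-and-pepper → speckle sequentially with
  deterministically derived sub-seeds. The components do not commute; the
  order is fixed and documented rather than implicit.
* `add_drift()` — deterministic
  $x(t) + \alpha t + \beta \sin(2\pi f t)$ at $t_i = i/f_s$, drift
  frequency 0.5 Hz by default, applied pre-normalization and never clipped.
  The default $\alpha = 0.05$/s and $\beta = 0.1$ are demonstration
  magnitudes only.
* `add_motion_artifacts()` — non-overlapping bursts (rejection-sampled
  placement) of zero-mean uniform jitter with half-range ~0.5 g
  (4.905 m/s²) in raw units, emulating device shaking.

The "20% intensity" test level maps per family to the natural parameter of
each model: $\sigma = 0.2$, `amount = 0.2` (the moderate of the
0.10/0.20/0.30 profiles), and `variance = 0.2`; treating the speckle
intensity as a variance (not an sd) is a documented choice.
Clipping to $[0, 1]$ after normalized-domain injection (default on)
preserves the pooling precondition. Noise is injected per window for
benchmark isolation; streams can be corrupted before segmentation by
applying the injectors to the raw columns instead.

## The robustness benchmark

`deviation_report()` compares a pooled clean signal against the pooled
noisy signal with four metrics: absolute mean difference, absolute
difference of population standard deviations, mean squared error, and
$1 - \rho$ (Pearson). MD and STD use absolute values so the report is
symmetric in its arguments. When either vector is constant the correlation
is undefined and the sentinel `NA` is reported — never a silent 0 or 1 —
and such windows are excluded from the $1-\rho$ averages (with a count).

`benchmark_poolings()` computes the metrics per window axis on identical
pooling grids, then averages over axes, windows and seeds; the aggregation
level is a documented choice. The no-noise condition compares the pooled
signal to itself and is exactly zero by construction; a
pooled-vs-decimated-raw variant is available behind `compare = "decimated"`
for summaries that implicitly use the raw signal as the reference. The
benchmark's reproducible surface is the *ordering* of methods — notably
that max pooling loses the most correlation under impulsive and Gaussian
noise while ECP and average pooling retain more — not any particular
numeric cell, which depends on the signals used. The ordering is asserted
on synthetic walking windows, where the pooled signal retains strong
periodic structure; on near-constant static-posture windows $1-\rho$
saturates for every method and the comparison is uninformative.

`stft_spectrogram()` provides the framewise DFT magnitude used to
visualize what each pooling method preserves; Hann taper, 32-sample
segments with hop 4 by default, honest frequency axis $0..f_s/2$.

## The synthetic generator

`generate_stream()` emits WISDM-format records: per user, one contiguous
bout per activity in randomized order (so majority labeling is exercised at
bout boundaries), timestamps at exact 1/fs spacing, and per-sample values
from a harmonic gait model: gravity projection + amplitude-scaled
fundamental with 2nd/3rd harmonics and a phase-shifted asymmetry term
(opposite signs for stair ascent/descent) + Gaussian jitter. The default
profiles are fixed documented constants chosen for qualitative realism, not
fitted to any corpus: walking ~2.0 Hz moderate amplitude, jogging ~2.8 Hz
high amplitude, stairs ~1.5 Hz with opposite asymmetry and opposite
vertical gravity bias, and static postures with distinct resting
orientations (sitting with the phone reclined, standing with a moderate
tilt away from the upright gait attitude) and small jitter. Class
durations are configurable, including a `class_proportions` option for
emulating the heavy Walking/Jogging skew of real recordings.

What the generator does **not** emulate: sampling-rate jitter by default
(a timestamp-jitter flag exists, affecting timestamps only — windowing is
index-based), missing data, device repositioning, inter-subject
variability beyond random phases, or the natural noise texture of real
recordings. Passing tests on this data therefore demonstrate mechanism
(boundedness, calibration, orderings, learnability), not field performance.

## Test and benchmark scales

The test suite runs entirely on synthetic data at desk scale: the
learnability check uses ~30 minutes of signal per class (6 users × 300 s
per activity at 20 Hz; ~4,300 windows of 100 samples at stride 50) with
the full 32/64/128 network widths, 10 epochs per run; the robustness
ordering uses 60 walking windows × 20 noise seeds; injector calibration
uses 10⁵-sample signals. Reported numbers in the README come from these
exact configurations.

## Known limitations

* **Static-posture degradation under heavy test noise.** With models
  trained on clean synthetic data, injecting Gaussian noise at
  $\sigma = 0.2$ (normalized units) into the test windows degrades the
  static postures *more* than the dynamic activities: $\sigma = 0.2$ is
  roughly 60× the static classes' intrinsic variation but comparable to
  the dynamic classes' oscillation amplitudes, so noisy static windows are
  pushed far out of the training distribution and are absorbed by gait
  classes. The finer-grained mechanism expected of real data does
  reproduce — Walking's top confusion under noise is Jogging, and
  dynamic–dynamic confusion grows — but the aggregate dynamic-vs-static
  ordering reported for models trained on real recordings (whose training
  data carries natural noise texture) does not emerge from this clean
  synthetic setup, and the corresponding acceptance-style test is expected
  to fail. This is a property of the generator's idealization, documented
  here rather than patched by tuning.
* The CNNs are reference implementations for CPU-scale experiments, not a
  production training stack: no GPU, no threading beyond BLAS, no
  checkpoint-resume.
* The benchmark's absolute deviation values depend on the synthetic
  signal family; only orderings and calibrations are asserted.
* Timestamps are trusted as monotone ticks; no resampling or gap
  imputation is performed (out of scope by design).
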