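#' Noise profile
#'
#' Bundles a noise family with its parameters and seed. The benchmark's
#' "20% intensity" level maps per family to the natural parameter of each
#' noise model: Gaussian `sigma = 0.2`, salt-and-pepper `amount = 0.2` (the
#' moderate profile among 0.10 / 0.20 / 0.30), and speckle
#' `variance = 0.2`.
#'
#' @param kind One of `"gaussian"`, `"salt_pepper"`, `"speckle"`,
#'   `"mixture"`, `"none"`.
#' @param sigma Gaussian standard deviation in normalized units (>= 0).
#' @param amount Fraction of samples corrupted by salt-and-pepper, in
#'   `[0, 1]`.
#' @param variance Speckle multiplicative noise variance (>= 0).
#' @param seed Optional integer seed; can also be supplied at injection time.
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(kind = c("gaussian", "salt_pepper", "speckle", "mixture", "none"),
                          sigma = 0.2, amount = 0.2, variance = 0.2, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, variance >= 0, amount >= 0, amount <= 1)
  structure(list(kind = kind, sigma = sigma, amount = amount,
                 variance = variance, seed = seed),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat("<noise_profile> ", x$kind, sep = "")
  if (x$kind %in% c("gaussian", "mixture")) cat(" sigma=", x$sigma, sep = "")
  if (x$kind %in% c("salt_pepper", "mixture")) cat(" amount=", x$amount, sep = "")
  if (x$kind %in% c("speckle", "mixture")) cat(" variance=", x$variance, sep = "")
  cat("\n")
  invisible(x)
}

run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean normal draws with standard deviation `sigma` to a
#' normalized signal, mimicking smooth fluctuations such as thermal noise.
#' With `clip = TRUE` (default) the output is clamped to `[0, 1]` to preserve
#' the bounded-pooling precondition; the pre-clip noise array is attached as
#' attribute `"noise"` for calibration diagnostics.
#'
#' @param signal Numeric vector in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0), default 0.2 (the
#'   benchmark's test-time level).
#' @param seed Optional integer seed; the same seed reproduces the output
#'   bit-for-bit.
#' @param clip Clamp the output to `[0, 1]` (default `TRUE`).
#' @return Noisy vector of the same length, with attribute `"noise"`.
#' @export
add_gaussian <- function(signal, sigma = 0.2, seed = NULL, clip = TRUE) {
  stopifnot(is.numeric(signal))
  if (sigma < 0) stop("sigma must be non-negative")
  noise <- run_seeded(seed, rnorm(length(signal), mean = 0, sd = sigma))
  out <- signal + noise
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "noise") <- noise
  out
}

#' Impulsive salt-and-pepper noise
#'
#' Replaces an independently chosen fraction of approximately `amount` of the
#' samples: exactly half of the replaced positions are set to 1 (salt) and
#' half to 0 (pepper), with an odd replaced count assigning the extra
#' position to salt or pepper at random. Unreplaced samples are untouched.
#' The replaced count follows Binomial(length, amount).
#'
#' @param signal Numeric vector in `[0, 1]`.
#' @param amount Corrupted fraction in `[0, 1]`, default 0.2 (moderate
#'   corruption; 0.10 and 0.30 are the light and heavy profiles).
#' @param seed Optional integer seed.
#' @return Noisy vector with attribute `"replaced"` (integer indices of the
#'   replaced positions).
#' @export
add_salt_pepper <- function(signal, amount = 0.2, seed = NULL) {
  stopifnot(is.numeric(signal))
  if (amount < 0 || amount > 1) stop("amount must be in [0, 1]")
  out <- run_seeded(seed, {
    hit <- which(runif(length(signal)) < amount)
    y <- signal
    if (length(hit) > 0) {
      hit <- hit[sample.int(length(hit))]  # random order so the half/half split is unbiased
      n_salt <- length(hit) %/% 2L
      if (length(hit) %% 2L == 1L) n_salt <- n_salt + sample(0:1, 1L)
      y[head(hit, n_salt)] <- 1
      y[setdiff(hit, head(hit, n_salt))] <- 0
    }
    attr(y, "replaced") <- sort(hit)
    y
  })
  out
}

#' Multiplicative speckle noise
#'
#' Computes `x + x * n` with `n ~ Normal(0, variance)` i.i.d., a
#' multiplicative corruption typical of transmission errors. An all-zero
#' signal is unchanged. For a constant signal `c` the pre-clip output
#' standard deviation is `c * sqrt(variance)` in closed form.
#'
#' @param signal Numeric vector in `[0, 1]`.
#' @param variance Variance of the multiplicative normal factor (>= 0),
#'   default 0.2.
#' @param seed Optional integer seed.
#' @param clip Clamp the output to `[0, 1]` (default `TRUE`).
#' @return Noisy vector with attribute `"noise"` (the multiplicative draws).
#' @export
add_speckle <- function(signal, variance = 0.2, seed = NULL, clip = TRUE) {
  stopifnot(is.numeric(signal))
  if (variance < 0) stop("variance must be non-negative")
  n <- run_seeded(seed, rnorm(length(signal), mean = 0, sd = sqrt(variance)))
  out <- signal + signal * n
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "noise") <- n
  out
}

#' Composite mixture noise
#'
#' Applies Gaussian, then salt-and-pepper, then speckle noise sequentially,
#' each at its profile intensity, with component sub-seeds derived
#' deterministically from `seed`. The application order matters (the
#' components do not commute) and is fixed to this documented sequence;
#' component intensities are taken from `profile`.
#'
#' @param signal Numeric vector in `[0, 1]`.
#' @param profile A [noise_profile()] holding `sigma`, `amount`, `variance`.
#' @param seed Optional integer seed.
#' @param clip Clamp after the Gaussian and speckle stages (default `TRUE`).
#' @return Noisy vector.
#' @export
add_mixture <- function(signal, profile = noise_profile("mixture"), seed = NULL,
                        clip = TRUE) {
  stopifnot(inherits(profile, "noise_profile"))
  s <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  p <- if (is.null(seed)) NULL else derive_seed(seed, 2L)
  k <- if (is.null(seed)) NULL else derive_seed(seed, 3L)
  out <- add_gaussian(signal, profile$sigma, seed = s, clip = clip)
  out <- add_salt_pepper(as.numeric(out), profile$amount, seed = p)
  out <- add_speckle(as.numeric(out), profile$variance, seed = k, clip = clip)
  as.numeric(out)
}

#' Apply a noise profile to a signal
#'
#' Dispatches to the matching injector; `kind = "none"` returns the signal
#' unchanged.
#'
#' @param signal Numeric vector in `[0, 1]`.
#' @param profile A [noise_profile()].
#' @param seed Optional integer seed overriding `profile$seed`.
#' @return Noisy vector (plain numeric).
#' @export
apply_noise <- function(signal, profile, seed = NULL) {
  stopifnot(inherits(profile, "noise_profile"))
  if (is.null(seed)) seed <- profile$seed
  out <- switch(profile$kind,
    none = signal,
    gaussian = add_gaussian(signal, profile$sigma, seed = seed),
    salt_pepper = add_salt_pepper(signal, profile$amount, seed = seed),
    speckle = add_speckle(signal, profile$variance, seed = seed),
    mixture = add_mixture(signal, profile, seed = seed)
  )
  as.numeric(out)
}

#' Displacement drift parameters
#'
#' Parameters of the deterministic baseline-drift model
#' `x_drifted(t) = x(t) + alpha * t + beta * sin(2 * pi * f * t)` which
#' emulates slow device displacement: a linear ramp plus a low-frequency
#' oscillation. The drift frequency defaults to 0.5 Hz. The defaults for
#' `alpha` and `beta` are demonstration magnitudes only and both are
#' mandatory inputs in benchmark configurations.
#'
#' @param alpha Linear slope per second.
#' @param beta Sinusoid amplitude.
#' @param f Drift frequency in Hz (must satisfy `f < fs / 2`), default 0.5.
#' @param fs Sampling rate in Hz.
#' @return An object of class `drift_params`.
#' @export
drift_params <- function(alpha = 0.05, beta = 0.1, f = 0.5, fs = 20) {
  stopifnot(fs > 0)
  if (f >= fs / 2) stop("drift frequency f must be below the Nyquist rate fs/2")
  structure(list(alpha = alpha, beta = beta, f = f, fs = fs),
            class = "drift_params")
}

#' Add deterministic displacement drift
#'
#' Exact evaluation of the drift model at sample times `t_i = i / fs`
#' (1-based sample index). No clipping is applied: drift is studied on the
#' raw, pre-normalization signal.
#'
#' @param signal Numeric vector (raw units).
#' @param params A [drift_params()].
#' @return Drifted vector.
#' @export
#' @examples
#' add_drift(rep(0, 20), drift_params(alpha = 1, beta = 0, fs = 20))[20]  # +1 at t = 1 s
add_drift <- function(signal, params) {
  stopifnot(inherits(params, "drift_params"))
  t <- seq_along(signal) / params$fs
  signal + params$alpha * t + params$beta * sin(2 * pi * params$f * t)
}

#' Motion-artifact parameters
#'
#' Short bursts of high-amplitude jitter emulating device shaking, applied in
#' raw acceleration units. The default amplitude of ~0.5 g (4.905 m/s^2) is
#' the shaking magnitude used in the false-positive robustness analysis.
#'
#' @param amplitude Half-range of the uniform jitter, raw units (> 0);
#'   default 4.905 (~0.5 g).
#' @param burst_duration Burst length in seconds.
#' @param bursts_per_window Number of bursts to place (>= 0).
#' @param fs Sampling rate in Hz.
#' @return An object of class `artifact_params`.
#' @export
artifact_params <- function(amplitude = 4.905, burst_duration = 0.5,
                            bursts_per_window = 1L, fs = 20) {
  stopifnot(amplitude > 0, fs > 0, bursts_per_window >= 0)
  if (round(burst_duration * fs) < 1) {
    stop("burst_duration must cover at least one sample at fs = ", fs, " Hz")
  }
  structure(list(amplitude = amplitude, burst_duration = burst_duration,
                 bursts_per_window = as.integer(bursts_per_window), fs = fs),
            class = "artifact_params")
}

#' Inject motion-artifact bursts
#'
#' Places `bursts_per_window` non-overlapping intervals of
#' `round(burst_duration * fs)` samples uniformly at random (overlaps
#' resolved by rejection sampling) and adds zero-mean uniform jitter with
#' half-range `amplitude` to each. Operates on raw (pre-normalization)
#' signals.
#'
#' @param signal Numeric vector in raw units.
#' @param params An [artifact_params()].
#' @param seed Optional integer seed; fixes both burst placement and jitter.
#' @return Corrupted vector with attribute `"burst_starts"`.
#' @export
add_motion_artifacts <- function(signal, params, seed = NULL) {
  stopifnot(inherits(params, "artifact_params"))
  L <- length(signal)
  blen <- max(1L, as.integer(round(params$burst_duration * params$fs)))
  k <- params$bursts_per_window
  if (k == 0L) {
    attr(signal, "burst_starts") <- integer(0)
    return(signal)
  }
  if (k * blen > L) {
    stop("window too short (", L, " samples) for ", k, " burst(s) of ", blen, " samples")
  }
  run_seeded(seed, {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < k) {
      cand <- sample.int(L - blen + 1L, 1L)
      if (!any(abs(cand - starts) < blen)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping bursts")
    }
    y <- signal
    for (s0 in starts) {
      idx <- s0:(s0 + blen - 1L)
      y[idx] <- y[idx] + runif(blen, -params$amplitude, params$amplitude)
    }
    attr(y, "burst_starts") <- sort(starts)
    y
  })
}

#' Corrupt every window of a `har_windows` object
#'
#' Applies a noise profile (normalized domain) or motion artifacts (raw
#' domain) to each axis of each window, with per-window/axis sub-seeds
#' derived deterministically from `seed` so the corruption is reproducible
#' and windows are corrupted independently.
#'
#' @param windows A `har_windows` object.
#' @param profile A [noise_profile()] or [artifact_params()].
#' @param seed Integer seed.
#' @return A `har_windows` object of the same shape.
#' @export
corrupt_windows <- function(windows, profile, seed = 1L) {
  stopifnot(inherits(windows, "har_windows"))
  v <- windows$values
  n <- n_windows(windows)
  for (j in seq_len(n)) {
    for (a in 1:3) {
      sub <- derive_seed(seed, j * 3L + a)
      v[a, , j] <- if (inherits(profile, "artifact_params")) {
        as.numeric(add_motion_artifacts(v[a, , j], profile, seed = sub))
      } else {
        apply_noise(v[a, , j], profile, seed = sub)
      }
    }
  }
  new_har_windows(v, windows$label, windows$user, windows$start)
}
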