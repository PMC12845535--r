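#' Signal deviation report
#'
#' Quantifies how far a pooled noisy signal deviates from the pooled clean
#' signal with four metrics (lower is better):
#' \describe{
#'   \item{md}{`|mean(a) - mean(b)|`, the absolute mean difference.}
#'   \item{std_diff}{`|sd(a) - sd(b)|` using population standard deviations.}
#'   \item{mse}{mean squared elementwise error.}
#'   \item{one_minus_rho}{`1 - Pearson correlation`, in `[0, 2]`.}
#' }
#' All four are symmetric in the two arguments and are 0 for identical
#' inputs. When either vector is constant the Pearson correlation is
#' undefined and `one_minus_rho` is reported as `NA` (an explicit sentinel,
#' never silently 0 or 1).
#'
#' @param pooled_clean,pooled_noisy Numeric vectors of equal length >= 2,
#'   finite.
#' @return An object of class `deviation_report`: named list with `md`,
#'   `std_diff`, `mse`, `one_minus_rho`.
#' @export
#' @examples
#' a <- sin(seq(0, 4 * pi, length.out = 50))
#' deviation_report(a, a + 0.1)  # md 0.1, std_diff 0, mse 0.01, 1 - rho 0
deviation_report <- function(pooled_clean, pooled_noisy) {
  a <- as.numeric(pooled_clean); b <- as.numeric(pooled_noisy)
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ", length(b))
  if (length(a) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("inputs must be finite")
  rho <- if (pop_sd(a) == 0 || pop_sd(b) == 0) NA_real_ else cor(a, b)
  structure(list(
    md = abs(mean(a) - mean(b)),
    std_diff = abs(pop_sd(a) - pop_sd(b)),
    mse = mean((a - b)^2),
    one_minus_rho = 1 - rho
  ), class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> MD=%.4f STD=%.4f MSE=%.4f 1-rho=%s\n",
              x$md, x$std_diff, x$mse,
              if (is.na(x$one_minus_rho)) "NA (constant input)"
              else sprintf("%.4f", x$one_minus_rho)))
  invisible(x)
}

#' Benchmark pooling methods under noise
#'
#' For every (noise profile, pooling spec) pair: corrupts each clean window
#' axis-wise with per-seed reproducible noise, pools the clean and the noisy
#' signal on the identical window grid, computes the four deviation metrics
#' per window axis, and averages them across axes, windows, and seeds.
#' A `"none"` profile compares the pooled signal against itself and yields
#' all-zero rows; a pooled-vs-decimated-raw variant is available via
#' `compare = "decimated"` (it compares the pooled clean signal against the
#' raw signal subsampled at the pooling stride, a nonzero baseline some
#' summaries implicitly use).
#'
#' The `one_minus_rho` column averages over windows where the correlation is
#' defined; windows with a constant pooled signal are excluded from that
#' metric (and counted in `n_undefined_rho`).
#'
#' @param windows A normalized `har_windows` object (all values in `[0, 1]`).
#' @param profiles Named list of [noise_profile()] objects.
#' @param specs Named list of [pooling_spec()] objects.
#' @param seeds Integer vector of noise seeds; the full table is a
#'   deterministic function of `(windows, profiles, specs, seeds)`.
#' @param compare `"self"` (default) or `"decimated"` for the no-noise
#'   reference (see above).
#' @return A `data.frame` with columns `noise_type`, `pooling`, `md`, `std`,
#'   `mse`, `one_minus_rho`, `n_undefined_rho`; one row per
#'   (profile, spec) pair.
#' @export
benchmark_poolings <- function(windows,
                               profiles = default_noise_profiles(),
                               specs = default_pooling_specs(),
                               seeds = 1:5,
                               compare = c("self", "decimated")) {
  compare <- match.arg(compare)
  stopifnot(inherits(windows, "har_windows"))
  n <- n_windows(windows)
  if (n == 0L) stop("empty signal set")
  v <- windows$values
  if (min(v) < 0 || max(v) > 1) stop("windows must be normalized to [0, 1]")
  if (is.null(names(profiles))) names(profiles) <- vapply(profiles, `[[`, "", "kind")
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "method")
  rows <- list()
  for (pn in names(profiles)) {
    profile <- profiles[[pn]]
    for (sn in names(specs)) {
      spec <- specs[[sn]]
      acc <- c(md = 0, std = 0, mse = 0)
      rho_sum <- 0; rho_n <- 0L; rho_na <- 0L; m <- 0L
      for (seed in seeds) {
        for (j in seq_len(n)) {
          for (a in 1:3) {
            clean <- v[a, , j]
            pooled_clean <- pool_1d(clean, spec)
            reference <- if (profile$kind == "none" && compare == "decimated") {
              clean[seq(1, by = spec$stride, length.out = length(pooled_clean))]
            } else {
              pooled_clean
            }
            noisy <- apply_noise(clean, profile, seed = derive_seed(seed, j * 3L + a))
            pooled_noisy <- pool_1d(noisy, spec)
            rep_ <- deviation_report(reference, pooled_noisy)
            acc <- acc + c(rep_$md, rep_$std_diff, rep_$mse)
            if (is.na(rep_$one_minus_rho)) rho_na <- rho_na + 1L
            else { rho_sum <- rho_sum + rep_$one_minus_rho; rho_n <- rho_n + 1L }
            m <- m + 1L
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        noise_type = pn, pooling = sn,
        md = acc[["md"]] / m, std = acc[["std"]] / m, mse = acc[["mse"]] / m,
        one_minus_rho = if (rho_n > 0) rho_sum / rho_n else NA_real_,
        n_undefined_rho = rho_na
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default noise conditions for the pooling benchmark
#'
#' The five conditions of the deviation study: no-noise baseline plus the
#' four families at their 20%-intensity parameterization.
#'
#' @return Named list of [noise_profile()] objects.
#' @export
default_noise_profiles <- function() {
  list(
    none = noise_profile("none"),
    gaussian = noise_profile("gaussian", sigma = 0.2),
    salt_pepper = noise_profile("salt_pepper", amount = 0.2),
    speckle = noise_profile("speckle", variance = 0.2),
    mixture = noise_profile("mixture")
  )
}

#' Default pooling specs for the benchmark
#'
#' The four compared methods with pooling size 2, stride 2.
#'
#' @param size Pooling size (default 2).
#' @return Named list of [pooling_spec()] objects.
#' @export
default_pooling_specs <- function(size = 2L) {
  list(
    max = pooling_spec("max", size),
    average = pooling_spec("average", size),
    ecp = pooling_spec("ecp", size),
    cmv = pooling_spec("cmv", size)
  )
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Frames the signal with a hop, applies a taper, and returns the magnitude
#' of the discrete Fourier transform per frame for frequencies 0 to `fs / 2`.
#' Used to visualize which frequency content each pooling method preserves.
#'
#' @param signal Numeric vector, length >= `segment_len`.
#' @param fs Sampling rate in Hz.
#' @param segment_len Frame length in samples (default 32).
#' @param hop Hop between frame starts in samples (default 4).
#' @param window Taper: `"hann"` (default) or `"rect"`.
#' @return An object of class `har_stft`: list with `magnitude`
#'   (frequencies x frames), `freq` (Hz, `0 .. fs/2`), and `time` (frame
#'   center times in seconds).
#' @export
stft_spectrogram <- function(signal, fs, segment_len = 32L, hop = 4L,
                             window = c("hann", "rect")) {
  window <- match.arg(window)
  segment_len <- as.integer(segment_len); hop <- as.integer(hop)
  stopifnot(hop >= 1L)
  L <- length(signal)
  if (segment_len > L) stop("segment_len (", segment_len, ") exceeds signal length (", L, ")")
  taper <- if (window == "hann") as.numeric(signal::hanning(segment_len)) else rep(1, segment_len)
  starts <- seq(1L, L - segment_len + 1L, by = hop)
  nf <- segment_len %/% 2L + 1L
  mag <- matrix(NA_real_, nf, length(starts))
  for (i in seq_along(starts)) {
    frame <- signal[starts[i]:(starts[i] + segment_len - 1L)] * taper
    mag[, i] <- Mod(fft(frame))[seq_len(nf)]
  }
  structure(list(
    magnitude = mag,
    freq = (seq_len(nf) - 1L) * fs / segment_len,
    time = (starts + segment_len / 2 - 1) / fs
  ), class = "har_stft")
}

#' @export
print.har_stft <- function(x, ...) {
  cat("<har_stft> ", nrow(x$magnitude), " frequencies (0-",
      max(x$freq), " Hz) x ", ncol(x$magnitude), " frames\n", sep = "")
  invisible(x)
}
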