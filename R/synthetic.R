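#' Activity signal profile
#'
#' Parameters of the harmonic gait model used by the synthetic generator.
#' Each sample of a dynamic activity is
#' `gravity + amplitude * (sin(2 pi f t + phase) + h2 sin(4 pi f t + 2 phase)
#' + h3 sin(6 pi f t + 3 phase)) + asymmetry * amplitude * sin(4 pi f t +
#' phase + pi/2) + jitter`, per axis; static postures (`base_freq = 0`) are
#' gravity plus jitter only. Amplitudes and gravity are in raw device units
#' (m/s^2-like, gravity ~9.81).
#'
#' @param name Activity label (one of the six canonical ones).
#' @param base_freq Fundamental frequency in Hz; 0 for static postures.
#' @param amplitude Numeric length-3 per-axis amplitude, raw units.
#' @param harmonic_weights Numeric length-2 relative amplitudes of the 2nd
#'   and 3rd harmonics.
#' @param gravity Numeric length-3 gravity projection, raw units.
#' @param jitter_sd Gaussian jitter standard deviation, raw units.
#' @param asymmetry Skew coefficient distinguishing stair ascent/descent
#'   (opposite signs); 0 otherwise.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, base_freq, amplitude, gravity,
                             harmonic_weights = c(0.5, 0.25),
                             jitter_sd = 0.3, asymmetry = 0) {
  stopifnot(name %in% .HAR_ACTIVITIES, base_freq >= 0, jitter_sd >= 0,
            length(amplitude) == 3L, length(gravity) == 3L,
            length(harmonic_weights) == 2L)
  structure(list(name = name, base_freq = base_freq,
                 amplitude = as.numeric(amplitude),
                 harmonic_weights = as.numeric(harmonic_weights),
                 gravity = as.numeric(gravity),
                 jitter_sd = jitter_sd, asymmetry = asymmetry),
            class = "activity_profile")
}

#' Default profiles for the six activities
#'
#' Fixed, documented constants chosen for qualitative realism of 20 Hz
#' pocket-worn accelerometer data rather than fitted to any corpus: walking
#' is a ~2 Hz moderate-amplitude gait, jogging ~2.8 Hz with distinctly
#' larger amplitude, sitting and standing are static postures identifiable
#' by gravity orientation - each has a resting phone attitude distinct from
#' the other and from the upright gait orientation - with small jitter, and
#' the stair activities share a ~1.5 Hz cadence but carry opposite-signed
#' asymmetry and opposite vertical-axis gravity bias.
#'
#' @return Named list of six [activity_profile()] objects.
#' @export
default_profiles <- function() {
  profs <- list(
    activity_profile("Walking", base_freq = 2.0,
                     amplitude = c(2.0, 3.5, 1.5), gravity = c(0.5, 9.81, 0.5),
                     jitter_sd = 0.4),
    activity_profile("Jogging", base_freq = 2.8,
                     amplitude = c(4.0, 7.0, 3.0), gravity = c(0.5, 9.81, 0.5),
                     harmonic_weights = c(0.5, 0.3), jitter_sd = 0.8),
    activity_profile("Sitting", base_freq = 0,
                     amplitude = c(0, 0, 0), gravity = c(1.5, 4.9, 8.3),
                     jitter_sd = 0.15),
    activity_profile("Standing", base_freq = 0,
                     amplitude = c(0, 0, 0), gravity = c(0.3, 9.0, 3.9),
                     jitter_sd = 0.1),
    activity_profile("Upstairs", base_freq = 1.5,
                     amplitude = c(2.5, 3.0, 2.0), gravity = c(0.5, 9.5, 1.8),
                     jitter_sd = 0.5, asymmetry = 0.4),
    activity_profile("Downstairs", base_freq = 1.5,
                     amplitude = c(2.5, 3.8, 2.0), gravity = c(0.5, 9.5, -1.8),
                     jitter_sd = 0.5, asymmetry = -0.4)
  )
  names(profs) <- vapply(profs, `[[`, "", "name")
  profs
}

#' Generator configuration
#'
#' @param fs Sampling rate in Hz (nominal 20).
#' @param n_users Number of simulated users.
#' @param seconds_per_activity Bout length per activity per user, in
#'   seconds; a scalar or a named vector over activities.
#' @param class_proportions Optional named numeric vector over activities
#'   summing to 1. When given, the total recording time per user
#'   (`sum of seconds_per_activity`) is redistributed across activities in
#'   these proportions, e.g. to emulate the heavy Walking/Jogging skew of
#'   real pocket-worn recordings.
#' @param seed Integer seed; the generated stream is a pure function of the
#'   configuration and this seed.
#' @param timestamp_jitter_sd Standard deviation (in seconds) of optional
#'   timestamp jitter emulating sampling-rate inconsistency; 0 (default)
#'   keeps the nominal-rate idealization. Affects timestamps only, never
#'   sample values or windowing, which are index-based.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(fs = 20, n_users = 3L, seconds_per_activity = 60,
                             class_proportions = NULL, seed = 1L,
                             timestamp_jitter_sd = 0) {
  stopifnot(fs > 0, n_users >= 1L, all(seconds_per_activity > 0),
            timestamp_jitter_sd >= 0)
  if (!is.null(class_proportions)) {
    stopifnot(!is.null(names(class_proportions)),
              abs(sum(class_proportions) - 1) < 1e-8,
              all(class_proportions > 0))
  }
  structure(list(fs = fs, n_users = as.integer(n_users),
                 seconds_per_activity = seconds_per_activity,
                 class_proportions = class_proportions,
                 seed = as.integer(seed),
                 timestamp_jitter_sd = timestamp_jitter_sd),
            class = "generator_config")
}

#' Generate a synthetic WISDM-format stream
#'
#' Simulates per-user streams of contiguous activity bouts (one bout per
#' activity, order randomized per user so window labeling is exercised at
#' bout boundaries). Sample values follow the harmonic model of
#' [activity_profile()] with random phases per bout and axis; timestamps are
#' integer ticks at `1 / fs` spacing (50 ms at 20 Hz, expressed in
#' nanosecond-like units of 50,000,000). The output is bit-reproducible for
#' a given `(profiles, config)` pair.
#'
#' @param profiles Named list of [activity_profile()]s, default
#'   [default_profiles()].
#' @param config A [generator_config()].
#' @return A record data.frame in the same shape as [read_wisdm_csv()]
#'   output: `user`, `activity`, `timestamp`, `x`, `y`, `z`.
#' @export
generate_stream <- function(profiles = default_profiles(),
                            config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  secs <- config$seconds_per_activity
  if (length(secs) == 1L) {
    secs <- stats::setNames(rep(secs, length(profiles)), names(profiles))
  }
  stopifnot(all(names(profiles) %in% names(secs)))
  if (!is.null(config$class_proportions)) {
    total <- sum(secs[names(profiles)])
    stopifnot(all(names(profiles) %in% names(config$class_proportions)))
    secs <- total * config$class_proportions[names(profiles)]
  }
  fs <- config$fs
  tick <- 5e7  # nominal inter-sample spacing in integer ticks (50 ms in ns)
  withr::with_seed(derive_seed(config$seed, 23L), {
    out <- vector("list", config$n_users)
    for (u in seq_len(config$n_users)) {
      order_u <- sample(names(profiles))
      bouts <- vector("list", length(order_u))
      for (bi in seq_along(order_u)) {
        prof <- profiles[[order_u[bi]]]
        n <- as.integer(round(secs[[prof$name]] * fs))
        if (n < 1L) stop("zero-duration bout for ", prof$name)
        t <- (seq_len(n) - 1L) / fs
        sig <- matrix(0, n, 3L)
        for (a in 1:3) {
          if (prof$base_freq > 0) {
            ph <- runif(1, 0, 2 * pi)
            w <- 2 * pi * prof$base_freq
            base <- sin(w * t + ph) +
              prof$harmonic_weights[1] * sin(2 * w * t + 2 * ph) +
              prof$harmonic_weights[2] * sin(3 * w * t + 3 * ph) +
              prof$asymmetry * sin(2 * w * t + ph + pi / 2)
            sig[, a] <- prof$gravity[a] + prof$amplitude[a] * base
          } else {
            sig[, a] <- prof$gravity[a]
          }
          sig[, a] <- sig[, a] + rnorm(n, 0, prof$jitter_sd)
        }
        bouts[[bi]] <- data.frame(activity = prof$name, x = sig[, 1],
                                  y = sig[, 2], z = sig[, 3])
      }
      ub <- do.call(rbind, bouts)
      n_u <- nrow(ub)
      ts <- (seq_len(n_u) - 1L) * tick
      if (config$timestamp_jitter_sd > 0) {
        ts <- ts + round(rnorm(n_u, 0, config$timestamp_jitter_sd * fs * tick / fs))
        ts <- cummax(ts)  # keep timestamps monotone non-decreasing
      }
      out[[u]] <- data.frame(user = u, activity = ub$activity, timestamp = ts,
                             x = ub$x, y = ub$y, z = ub$z)
    }
    res <- do.call(rbind, out)
    res$activity <- factor(res$activity, levels = .HAR_ACTIVITIES)
    rownames(res) <- NULL
    res
  })
}

#' Write a generation manifest
#'
#' Records the seed, configuration, and per-class record counts of a
#' generated stream as JSON, for reproducibility audits.
#'
#' @param records Data frame from [generate_stream()].
#' @param config The [generator_config()] used.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, config, path) {
  manifest <- list(
    seed = config$seed,
    fs = config$fs,
    n_users = config$n_users,
    seconds_per_activity = config$seconds_per_activity,
    n_records = nrow(records),
    class_counts = as.list(table(records$activity))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
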