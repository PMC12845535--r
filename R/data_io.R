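#' Read a WISDM-format accelerometer CSV
#'
#' Parses raw accelerometer recordings in the WISDM dialect: comma-separated
#' rows `user, activity, timestamp, x, y, z` with no header. The public raw
#' file has a few quirks that are tolerated here: rows may end in a trailing
#' semicolon, and blank lines may appear between records. Rows with unparsable
#' numeric fields, fewer than six fields, or an activity label outside the six
#' canonical ones are skipped; the number of skipped rows is reported via a
#' message and attached to the result as attribute `"skipped"`.
#'
#' Records are returned sorted by `(user, timestamp)` (stable sort, so ties
#' keep file order). Timestamps are kept as numeric ticks and never resampled;
#' all downstream windowing is index-based.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the skip-count message.
#' @return A `data.frame` with columns `user` (integer), `activity` (factor
#'   with the six canonical levels), `timestamp` (numeric ticks), `x`, `y`,
#'   `z` (numeric acceleration, raw device units), with attribute `skipped`.
#' @seealso [write_wisdm_csv()], [segment_windows()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("1,Walking,0,0.1,9.8,0.2;", "1,Walking,50,0.2,9.7,0.1;"), f)
#' read_wisdm_csv(f)
read_wisdm_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  n_blank <- sum(lines == "")
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    stop("no rows in file: ", path)
  }
  # real-WISDM dialect: rows may be terminated by one or more semicolons
  lines <- sub(";+$", "", lines)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ok_len <- lengths(parts) >= 6L
  get <- function(i) vapply(parts[ok_len], function(p) trimws(p[[i]]), character(1))
  user <- suppressWarnings(as.integer(get(1)))
  activity <- get(2)
  timestamp <- suppressWarnings(as.numeric(get(3)))
  ax <- suppressWarnings(as.numeric(get(4)))
  ay <- suppressWarnings(as.numeric(get(5)))
  az <- suppressWarnings(as.numeric(get(6)))
  valid <- !is.na(user) & user > 0L & activity %in% .HAR_ACTIVITIES &
    !is.na(timestamp) & !is.na(ax) & !is.na(ay) & !is.na(az)
  skipped <- sum(!ok_len) + sum(!valid)
  if (sum(valid) == 0L) {
    stop("no valid rows in file: ", path, " (", skipped, " rows skipped)")
  }
  df <- data.frame(
    user = user[valid],
    activity = factor(activity[valid], levels = .HAR_ACTIVITIES),
    timestamp = timestamp[valid],
    x = ax[valid], y = ay[valid], z = az[valid]
  )
  ord <- order(df$user, df$timestamp)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!quiet && skipped > 0L) {
    message("read_wisdm_csv: skipped ", skipped, " invalid row(s)",
            if (n_blank > 0L) paste0(" (plus ", n_blank, " blank line(s))"))
  }
  attr(df, "skipped") <- skipped
  df
}

#' Write records in the WISDM CSV dialect
#'
#' Inverse of [read_wisdm_csv()]: writes `user, activity, timestamp, x, y, z`
#' rows without a header. The `"semicolon"` dialect terminates every row with
#' `;` as the public raw file does; the reader accepts both.
#'
#' @param records Data frame as returned by [read_wisdm_csv()] or
#'   [generate_stream()].
#' @param path Output path.
#' @param dialect `"plain"` or `"semicolon"`.
#' @return `path`, invisibly.
#' @export
write_wisdm_csv <- function(records, path, dialect = c("plain", "semicolon")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("user", "activity", "timestamp", "x", "y", "z") %in% names(records)))
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  num <- function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15)
  rows <- paste(records$user, as.character(records$activity),
                num(records$timestamp), num(records$x), num(records$y),
                num(records$z), sep = ",")
  if (dialect == "semicolon") rows <- paste0(rows, ";")
  writeLines(rows, path)
  invisible(path)
}

#' Segment per-user streams into fixed-length labeled windows
#'
#' Slides a window of `window_len` samples with step `stride` over each user's
#' stream independently (segmentation never crosses user boundaries). Short
#' trailing segments are dropped, so each user contributes
#' `floor((N - window_len) / stride) + 1` windows when their stream has
#' `N >= window_len` samples and none otherwise. Each window is labeled by
#' majority vote over its per-sample activity labels; ties are broken in
#' favor of the tied label occurring earliest within the window.
#'
#' @param records Data frame of sensor records (see [read_wisdm_csv()]),
#'   assumed sorted by `(user, timestamp)`.
#' @param window_len Window length in samples (>= 2). The recording protocol
#'   uses 10-s windows of 200 samples at 20 Hz; the sliding-window experiments
#'   use 100-sample windows with stride 50 (50% overlap).
#' @param stride Step between window starts, `1 <= stride <= window_len`.
#' @return A `har_windows` object: list with `values` (3 x L x n array, rows
#'   x/y/z), `label` (factor), `user` (integer), `start` (1-based sample
#'   offset within the user's stream).
#' @export
segment_windows <- function(records, window_len = 100L, stride = 50L) {
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  stopifnot(window_len >= 2L, stride >= 1L, stride <= window_len)
  vals <- list(); labs <- list(); users <- list(); starts <- list()
  for (u in unique(records$user)) {
    s <- records[records$user == u, , drop = FALSE]
    n <- nrow(s)
    if (n < window_len) next
    n_win <- (n - window_len) %/% stride + 1L
    sig <- t(as.matrix(s[, c("x", "y", "z")]))  # 3 x n
    lab_codes <- as.integer(s$activity)
    w_vals <- array(NA_real_, dim = c(3L, window_len, n_win))
    w_lab <- integer(n_win)
    for (j in seq_len(n_win)) {
      i0 <- (j - 1L) * stride + 1L
      idx <- i0:(i0 + window_len - 1L)
      w_vals[, , j] <- sig[, idx]
      w_lab[j] <- majority_label(lab_codes[idx])
    }
    vals[[length(vals) + 1L]] <- w_vals
    labs[[length(labs) + 1L]] <- w_lab
    users[[length(users) + 1L]] <- rep(as.integer(u), n_win)
    starts[[length(starts) + 1L]] <- (seq_len(n_win) - 1L) * stride + 1L
  }
  if (length(vals) == 0L) {
    return(new_har_windows(array(0, dim = c(3L, window_len, 0L)),
                           factor(character(0), levels = .HAR_ACTIVITIES),
                           integer(0), integer(0)))
  }
  values <- array(unlist(vals), dim = c(3L, window_len, sum(lengths(labs))))
  new_har_windows(values,
                  factor(.HAR_ACTIVITIES[unlist(labs)], levels = .HAR_ACTIVITIES),
                  unlist(users), unlist(starts))
}

# Majority vote over integer label codes; ties go to the code whose first
# occurrence in the window is earliest.
majority_label <- function(codes) {
  counts <- tabulate(codes, nbins = length(.HAR_ACTIVITIES))
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  firsts <- vapply(top, function(k) match(k, codes), integer(1))
  top[which.min(firsts)]
}

new_har_windows <- function(values, label, user, start) {
  stopifnot(length(dim(values)) == 3L, dim(values)[1] == 3L)
  structure(list(values = values, label = label, user = user, start = start),
            class = "har_windows")
}

#' @export
print.har_windows <- function(x, ...) {
  cat("<har_windows> ", n_windows(x), " windows of length ", dim(x$values)[2],
      " (", length(unique(x$user)), " user(s))\n", sep = "")
  if (n_windows(x) > 0) print(table(x$label))
  invisible(x)
}

#' Number of windows in a `har_windows` object
#' @param x A `har_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(x) dim(x$values)[3]

#' Subset windows
#' @param x A `har_windows` object.
#' @param i Index vector of windows to keep.
#' @param ... Unused.
#' @return A `har_windows` object with the selected windows.
#' @export
`[.har_windows` <- function(x, i, ...) {
  new_har_windows(x$values[, , i, drop = FALSE], x$label[i], x$user[i], x$start[i])
}

#' Fit global per-axis min-max normalization parameters
#'
#' Computes the global minimum and maximum per axis (x, y, z) over all
#' samples of the supplied (training) windows. Normalization is fit on the
#' training split only and applied with clipping to held-out data, which
#' guarantees the `[0, 1]` precondition of the bounded pooling reducers on
#' unseen windows while preserving inter-window amplitude differences.
#'
#' @param windows A `har_windows` object with at least one window.
#' @return An object of class `minmax_params`: list with numeric `min` and
#'   `max` of length 3 (named x, y, z).
#' @export
fit_minmax <- function(windows) {
  stopifnot(inherits(windows, "har_windows"), n_windows(windows) >= 1L)
  mins <- apply(windows$values, 1, min)
  maxs <- apply(windows$values, 1, max)
  names(mins) <- names(maxs) <- c("x", "y", "z")
  degenerate <- maxs <= mins
  if (any(degenerate)) {
    stop("constant axis (no spread), cannot fit min-max normalization: ",
         paste(names(mins)[degenerate], collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' @export
print.minmax_params <- function(x, ...) {
  cat("<minmax_params>\n")
  print(rbind(min = x$min, max = x$max))
  invisible(x)
}

#' Apply min-max normalization to windows
#'
#' Maps every value to `(v - min) / (max - min)` per axis. With `clip = TRUE`
#' (the default) values from held-out data that fall outside the training
#' range are clamped to `[0, 1]`, so the output always satisfies the bounded
#' pooling precondition. With `clip = FALSE` any out-of-range output is an
#' error, since it would void the boundedness guarantee downstream.
#'
#' @param windows A `har_windows` object.
#' @param params `minmax_params` from [fit_minmax()].
#' @param clip Clamp out-of-range values (default `TRUE`).
#' @return A `har_windows` object with all values in `[0, 1]`.
#' @export
apply_minmax <- function(windows, params, clip = TRUE) {
  stopifnot(inherits(windows, "har_windows"), inherits(params, "minmax_params"))
  rng <- params$max - params$min
  v <- sweep(windows$values, 1, params$min, "-")
  v <- sweep(v, 1, rng, "/")
  if (clip) {
    v[v < 0] <- 0
    v[v > 1] <- 1
  } else if (n_windows(windows) > 0 && (min(v) < 0 || max(v) > 1)) {
    stop("values outside [0, 1] after normalization and clip = FALSE; ",
         "bounded pooling precondition would be violated")
  }
  new_har_windows(v, windows$label, windows$user, windows$start)
}

#' Inverse-frequency class weights
#'
#' Computes `w_c = N / (K * n_c)` where `N` is the total number of labels,
#' `K` the number of classes present, and `n_c` the count of class `c`.
#' Balanced classes get weight 1; minority classes get weight > 1 so that a
#' class-weighted cross-entropy loss penalizes their misclassification more
#' heavily.
#'
#' @param labels Factor or character vector of activity labels (non-empty).
#' @return Named numeric vector of weights, one per class present.
#' @export
#' @examples
#' class_weights(c("A", "A", "A", "B"))  # A: 0.667, B: 2
class_weights <- function(labels) {
  if (length(labels) == 0L) stop("empty label sequence")
  counts <- table(as.character(labels))
  n <- length(labels)
  k <- length(counts)
  w <- n / (k * as.numeric(counts))
  names(w) <- names(counts)
  w
}

#' Write windows to a flat columnar CSV
#'
#' One row per window: `user, label, start`, then the 3 x L values flattened
#' row-major (all x samples, then y, then z).
#'
#' @param windows A `har_windows` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  L <- dim(windows$values)[2]
  n <- n_windows(windows)
  flat <- matrix(aperm(windows$values, c(3, 2, 1)), nrow = n)  # n x (L*3), x block first
  df <- data.frame(user = windows$user, label = as.character(windows$label),
                   start = windows$start)
  colnames(flat) <- paste0(rep(c("x", "y", "z"), each = L), rep(seq_len(L), 3))
  write.csv(cbind(df, as.data.frame(flat)), path, row.names = FALSE)
  invisible(path)
}

#' Read windows written by [write_windows_csv()]
#'
#' @param path CSV path.
#' @return A `har_windows` object.
#' @export
read_windows_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  n <- nrow(df)
  L <- (ncol(df) - 3L) %/% 3L
  flat <- as.matrix(df[, -(1:3), drop = FALSE])
  values <- aperm(array(flat, dim = c(n, L, 3L)), c(3, 2, 1))
  new_har_windows(values, factor(df$label, levels = .HAR_ACTIVITIES),
                  as.integer(df$user), as.integer(df$start))
}
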