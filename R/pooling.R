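#' Extrema contrast pooling (ECP) reducer
#'
#' Reduces a window of values to `(max + min) / 2 - alpha * (max - min)^2`:
#' the midpoint of the extrema penalized by the squared range. With
#' `alpha = 1/2` (the default) and input in `[0, 1]` the output is guaranteed
#' to stay in `[0, 1]`: the midpoint lies in `[0, 1]`, the squared range in
#' `[0, 1]`, and the maximum possible subtraction is 1/2, attained at maximum
#' contrast (`{0, 1}` pools to 0). A flat window pools to its constant value.
#'
#' The range penalty makes ECP sensitive to sharp local transitions while
#' remaining robust to isolated outliers compared to max pooling.
#'
#' @param values Numeric vector, at least one value. Expected in `[0, 1]`.
#' @param alpha Range-penalty coefficient in `(0, 1/2]`; `1/2` guarantees the
#'   `[0, 1]` bound. Exposed for ablation only.
#' @param strict If `TRUE`, error when any value falls outside `[0, 1]`
#'   (recommended for signal-level use; inside CNNs post-ReLU activations are
#'   not range-guaranteed and the formula is applied as-is).
#' @return A single numeric value.
#' @seealso [cmv()], [pool_1d()], [pool_2d()]
#' @export
#' @examples
#' ecp(c(0, 1))           # 0: maximum contrast
#' ecp(c(0.2, 0.6, 0.4))  # 0.4 - 0.5 * 0.16 = 0.32
ecp <- function(values, alpha = 0.5, strict = FALSE) {
  check_reducer_input(values, strict)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 0.5)
  M <- max(values); m <- min(values)
  (M + m) / 2 - alpha * (M - m)^2
}

#' Center-minus-variation (CMV) pooling reducer
#'
#' Reduces a window to `(max + min) / 2 - sd(values)` where `sd` is the
#' population standard deviation (divide by `n`). For input in `[0, 1]` the
#' population sd is at most 0.5 (attained by `{0, 1}`), so the output stays
#' in `[0, 1]`; the sample standard deviation would break this bound
#' (sample sd of `{0, 1}` is about 0.707). Subtracting the intra-window
#' variation suppresses noise-driven fluctuations, akin to a variance-aware
#' smoothing of the extrema midpoint. For two-element windows CMV equals the
#' window minimum exactly (midpoint minus half the range).
#'
#' @inheritParams ecp
#' @return A single numeric value.
#' @seealso [ecp()], [pool_1d()], [pool_2d()]
#' @export
#' @examples
#' cmv(c(0, 1))  # 0: population sd of {0, 1} is 0.5
#' cmv(c(0.2, 0.4, 0.6))  # 0.4 - sqrt(0.08 / 3)
cmv <- function(values, strict = FALSE) {
  check_reducer_input(values, strict)
  M <- max(values); m <- min(values)
  (M + m) / 2 - pop_sd(values)
}

check_reducer_input <- function(values, strict) {
  if (length(values) == 0L) stop("empty pooling window")
  if (!is.numeric(values) || anyNA(values)) stop("pooling window must be numeric and finite")
  if (strict && (min(values) < 0 || max(values) > 1)) {
    stop("strict mode: pooling input outside [0, 1]; normalize first")
  }
  invisible(TRUE)
}

#' Pooling specification
#'
#' Bundles the pooling method, window size, stride, and (for ECP) the
#' range-penalty coefficient into a reusable spec consumed by [pool_1d()],
#' [pool_2d()] and the CNN builders.
#'
#' @param method One of `"max"`, `"average"`, `"ecp"`, `"cmv"`.
#' @param size Pooling window length (1D) or square side (2D), >= 1.
#' @param stride Step between windows, >= 1; defaults to `size`
#'   (non-overlapping).
#' @param alpha ECP coefficient in `(0, 1/2]`; ignored by other methods.
#' @return An object of class `pooling_spec`.
#' @export
#' @examples
#' pooling_spec("ecp", size = 2)
pooling_spec <- function(method = c("max", "average", "ecp", "cmv"),
                         size = 2L, stride = size, alpha = 0.5) {
  method <- match.arg(method)
  size <- as.integer(size); stride <- as.integer(stride)
  stopifnot(size >= 1L, stride >= 1L, alpha > 0, alpha <= 0.5)
  structure(list(method = method, size = size, stride = stride, alpha = alpha),
            class = "pooling_spec")
}

#' @export
print.pooling_spec <- function(x, ...) {
  cat("<pooling_spec> ", x$method, " size=", x$size, " stride=", x$stride,
      if (x$method == "ecp") paste0(" alpha=", x$alpha), "\n", sep = "")
  invisible(x)
}

# Vectorized reduction of a size x n window matrix to an n-vector.
# Shared by the public pooling transforms and the CNN pooling layers.
reduce_windows <- function(wm, method, alpha = 0.5) {
  if (is.null(dim(wm))) wm <- matrix(wm, nrow = 1L)
  rows <- asplit(wm, 1)
  switch(method,
    max = Reduce(pmax, rows),
    average = colMeans(wm),
    ecp = {
      M <- Reduce(pmax, rows); m <- Reduce(pmin, rows)
      (M + m) / 2 - alpha * (M - m)^2
    },
    cmv = {
      M <- Reduce(pmax, rows); m <- Reduce(pmin, rows)
      mu <- colMeans(wm)
      sig <- sqrt(pmax(colMeans(wm^2) - mu^2, 0))
      (M + m) / 2 - sig
    },
    stop("unknown pooling method: ", method)
  )
}

#' Strided 1D pooling over a multi-channel signal
#'
#' Applies the reducer of `spec` to consecutive windows of each channel
#' independently. The output length is `floor((L - size) / stride) + 1`;
#' trailing samples that do not fill a window are dropped.
#'
#' @param signal Numeric vector or `C x L` matrix (channels in rows).
#' @param spec A [pooling_spec()].
#' @return A `C x L'` matrix (or a vector if the input was a vector).
#' @export
#' @examples
#' pool_1d(c(0, 1, 1, 1), pooling_spec("average", 2))  # 0.5 1.0
pool_1d <- function(signal, spec) {
  stopifnot(inherits(spec, "pooling_spec"))
  was_vector <- is.null(dim(signal))
  x <- if (was_vector) matrix(signal, nrow = 1L) else as.matrix(signal)
  L <- ncol(x)
  if (L < spec$size) stop("signal length ", L, " shorter than pooling size ", spec$size)
  n_out <- (L - spec$size) %/% spec$stride + 1L
  idx <- outer(seq_len(spec$size), (seq_len(n_out) - 1L) * spec$stride, "+")  # size x n_out
  out <- matrix(NA_real_, nrow(x), n_out)
  for (c_i in seq_len(nrow(x))) {
    wm <- matrix(x[c_i, idx], nrow = spec$size)
    out[c_i, ] <- reduce_windows(wm, spec$method, spec$alpha)
  }
  if (was_vector) drop(out) else out
}

#' Strided 2D pooling over a multi-channel map
#'
#' Applies the reducer of `spec` to every `size x size` patch with the given
#' stride in both spatial directions, per channel.
#'
#' @param map `C x H x W` array, or an `H x W` matrix (treated as one channel).
#' @param spec A [pooling_spec()].
#' @return A `C x H' x W'` array (or `H' x W'` matrix for matrix input).
#' @export
#' @examples
#' pool_2d(matrix(c(0, 1, 1, 0), 2), pooling_spec("max", 2))  # 1
pool_2d <- function(map, spec) {
  stopifnot(inherits(spec, "pooling_spec"))
  was_matrix <- is.matrix(map)
  a <- if (was_matrix) array(map, dim = c(1L, dim(map))) else map
  stopifnot(length(dim(a)) == 3L)
  C <- dim(a)[1]; H <- dim(a)[2]; W <- dim(a)[3]
  s <- spec$size
  if (H < s || W < s) stop("spatial dims (", H, "x", W, ") smaller than pooling size ", s)
  Ho <- (H - s) %/% spec$stride + 1L
  Wo <- (W - s) %/% spec$stride + 1L
  n <- C * Ho * Wo
  wm <- matrix(NA_real_, s * s, n)
  r0 <- (seq_len(Ho) - 1L) * spec$stride
  c0 <- (seq_len(Wo) - 1L) * spec$stride
  k <- 0L
  for (kj in seq_len(s)) {
    for (ki in seq_len(s)) {
      k <- k + 1L
      wm[k, ] <- as.vector(a[, r0 + ki, c0 + kj, drop = FALSE])
    }
  }
  out <- reduce_windows(wm, spec$method, spec$alpha)
  out <- array(out, dim = c(C, Ho, Wo))
  if (was_matrix) out[1, , ] else out
}
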