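#' Histogram encoder configuration
#'
#' Controls how a normalized tri-axial window is converted into a 3-channel
#' histogram image. The default discretizes each axis into 100 uniform bins
#' over `[0, 1]` and reshapes the 100 counts row-major into a 10 x 10 grid,
#' giving genuine 2D structure for 3 x 3 convolutions while keeping adjacent
#' bins adjacent in the image. The grid shape must multiply out to `bins`.
#'
#' @param bins Number of uniform bins over `[0, 1]` (>= 2), default 100.
#'   Bin counts of 50 and 200 are supported ablation settings.
#' @param grid Integer vector `c(rows, cols)` with `rows * cols == bins`.
#' @param count_normalization `"per-channel-max"` (default: divide counts by
#'   the window length, then rescale each channel by its maximum so the
#'   brightest pixel is 1) or `"per-length"` (divide by window length only).
#'   Both keep all pixels in `[0, 1]`, the precondition of the bounded
#'   pooling layers downstream.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(bins = 100L, grid = NULL,
                           count_normalization = c("per-channel-max", "per-length")) {
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  if (is.null(grid)) {
    r <- floor(sqrt(bins))
    while (bins %% r != 0L) r <- r - 1L
    grid <- c(r, bins %/% r)
  }
  grid <- as.integer(grid)
  if (length(grid) != 2L || prod(grid) != bins) {
    stop("grid rows * cols must equal bins (", bins, ")")
  }
  structure(list(bins = bins, grid = grid,
                 count_normalization = match.arg(count_normalization)),
            class = "encoder_config")
}

#' Uniform histogram of normalized values
#'
#' Counts values into `bins` uniform bins over `[0, 1]`. Bins are half-open
#' `[e_i, e_{i+1})` with the last bin closed, so a value of exactly 1 falls
#' in the last bin. Counts always sum to the number of values.
#'
#' @param values Numeric vector in `[0, 1]`, non-empty.
#' @param bins Number of bins (>= 2).
#' @return Integer vector of counts of length `bins`, with the bin edges
#'   (length `bins + 1`) attached as attribute `"edges"`.
#' @export
#' @examples
#' axis_histogram(rep(0.555, 200), 100)[56]  # all 200 in bin 56 (index 55, 0-based)
axis_histogram <- function(values, bins = 100L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  if (length(values) == 0L) stop("empty value vector")
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop("values must be normalized to [0, 1] before binning")
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  attr(counts, "edges") <- edges
  counts
}

#' Encode a normalized window as a 3-channel histogram image
#'
#' Computes one uniform histogram per axis of a normalized window, normalizes
#' the counts (see [encoder_config()]), reshapes each count vector row-major
#' into the configured grid, and stacks the three grids into a 3-channel
#' image: x -> channel 1 (R), y -> channel 2 (G), z -> channel 3 (B). The
#' encoding is a pure function of the multiset of values per axis: shuffling
#' samples in time leaves the image unchanged, which is exactly the
#' redundancy-discarding property the representation is designed for.
#'
#' @param window A 3 x L numeric matrix with values in `[0, 1]`, or a
#'   `har_windows` object containing exactly one window.
#' @param config An [encoder_config()].
#' @return An object of class `har_histogram_image`: list with `pixels`
#'   (3 x rows x cols array in `[0, 1]`), `counts` (3 x bins raw counts),
#'   and `bin_edges`.
#' @export
encode_rgb <- function(window, config = encoder_config()) {
  if (inherits(window, "har_windows")) {
    stopifnot(n_windows(window) == 1L)
    window <- window$values[, , 1]
  }
  stopifnot(is.matrix(window), nrow(window) == 3L)
  if (anyNA(window) || min(window) < 0 || max(window) > 1) {
    stop("window must be normalized to [0, 1] before encoding")
  }
  L <- ncol(window)
  counts <- t(vapply(1:3, function(a) as.numeric(axis_histogram(window[a, ], config$bins)),
                     numeric(config$bins)))  # 3 x bins
  pix <- counts / L
  if (config$count_normalization == "per-channel-max") {
    mx <- apply(pix, 1, max)
    mx[mx == 0] <- 1
    pix <- pix / mx
  }
  # row-major reshape: bin b -> (row (b-1) %/% cols + 1, col (b-1) %% cols + 1)
  gr <- config$grid[1]; gc <- config$grid[2]
  pixels <- array(NA_real_, dim = c(3L, gr, gc))
  for (a in 1:3) {
    pixels[a, , ] <- matrix(pix[a, ], nrow = gr, ncol = gc, byrow = TRUE)
  }
  structure(list(pixels = pixels, counts = counts,
                 bin_edges = seq(0, 1, length.out = config$bins + 1L)),
            class = "har_histogram_image")
}

#' @export
print.har_histogram_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<har_histogram_image> 3 x ", d[2], " x ", d[3], " (",
      ncol(x$counts), " bins/channel)\n", sep = "")
  invisible(x)
}

#' Encode many windows into an image stack
#'
#' Vectorized convenience over [encode_rgb()] for model input.
#'
#' @param windows A normalized `har_windows` object.
#' @param config An [encoder_config()].
#' @return A `3 x rows x cols x n` array of pixel values in `[0, 1]`.
#' @export
encode_windows <- function(windows, config = encoder_config()) {
  n <- n_windows(windows)
  out <- array(NA_real_, dim = c(3L, config$grid[1], config$grid[2], n))
  for (j in seq_len(n)) {
    out[, , , j] <- encode_rgb(windows$values[, , j], config)$pixels
  }
  out
}

#' Write a histogram image as an 8-bit PNG (for inspection only)
#'
#' Quantizes the exact pixel array to 8 bits and writes a PNG. Training
#' always consumes the exact numeric arrays, never the PNG.
#'
#' @param image A `har_histogram_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files")
  }
  # png::writePNG expects H x W x channels in [0, 1]
  arr <- aperm(image$pixels, c(2, 3, 1))
  png::writePNG(arr, path)
  invisible(path)
}
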