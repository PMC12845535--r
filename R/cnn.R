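#' Build the reference 1D CNN for raw signal windows
#'
#' Two convolutional blocks (default 32 and 64 filters, kernel sizes 5 and 3,
#' stride 1, 'same' zero padding, ReLU) each followed by a pooling layer
#' (default size 2, stride 2) whose reducer is pluggable via a
#' [pooling_spec()], then a fully connected ReLU layer (default 128 units)
#' and a softmax output. For a 3 x 100 input with the defaults the feature
#' map after the second pooling is 64 x 25, giving a flatten width of 1600.
#' Weight initialization is He-scaled normal, keyed to `seed`.
#'
#' @param input_len Window length in samples; the post-pooling lengths must
#'   stay >= 1.
#' @param pooling A [pooling_spec()] used for both pooling layers.
#' @param filters Integer vector of two filter counts.
#' @param kernels Integer vector of two odd kernel sizes.
#' @param fc Fully connected width.
#' @param classes Character vector of class labels (defaults to the six
#'   activities).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `har_cnn` (untrained).
#' @seealso [train_cnn()], [predict.har_cnn()], [build_cnn_2d()]
#' @export
build_cnn_1d <- function(input_len, pooling = pooling_spec("ecp", 2L),
                         filters = c(32L, 64L), kernels = c(5L, 3L),
                         fc = 128L, classes = wisdm_activities(), seed = 1L) {
  stopifnot(inherits(pooling, "pooling_spec"), length(filters) == 2L,
            length(kernels) == 2L, all(kernels %% 2L == 1L))
  L1 <- pooled_len(input_len, pooling)
  if (L1 < 1L) stop("input_len ", input_len, " incompatible with pooling layer 1")
  L2 <- pooled_len(L1, pooling)
  if (L2 < 1L) stop("input_len ", input_len, " incompatible with pooling layer 2")
  flat <- filters[2] * L2
  n_classes <- length(classes)
  params <- withr::with_seed(derive_seed(seed, 11L), list(
    W1 = he_init(filters[1], 3L * kernels[1]),
    b1 = numeric(filters[1]),
    W2 = he_init(filters[2], filters[1] * kernels[2]),
    b2 = numeric(filters[2]),
    Wf = he_init(fc, flat),
    bf = numeric(fc),
    Wo = he_init(n_classes, fc),
    bo = numeric(n_classes)
  ))
  structure(list(arch = "1d", input_len = as.integer(input_len),
                 pooling = pooling, filters = as.integer(filters),
                 kernels = as.integer(kernels), fc = as.integer(fc),
                 classes = classes, n_classes = n_classes,
                 shapes = list(L1 = L1, L2 = L2, flat = flat),
                 params = params, trained = FALSE, history = NULL,
                 seed = as.integer(seed)),
            class = "har_cnn")
}

#' Build the reference 2D CNN for histogram images
#'
#' Same layer chain as [build_cnn_1d()] but with 3 x 3 convolutions over
#' 3-channel histogram images and square pooling windows. For a 3 x 10 x 10
#' input with 2 x 2 pooling the spatial path is 10 -> 5 -> 2 (floor), giving
#' a flatten width of 64 * 4 = 256 with the default filters.
#'
#' @param input_shape Integer vector `c(rows, cols)` of the image.
#' @param pooling A [pooling_spec()] (size interpreted as the square side).
#' @param filters Integer vector of two filter counts.
#' @param kernel Odd kernel side (default 3).
#' @param fc Fully connected width.
#' @param classes Character vector of class labels.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `har_cnn` (untrained).
#' @export
build_cnn_2d <- function(input_shape = c(10L, 10L),
                         pooling = pooling_spec("ecp", 2L),
                         filters = c(32L, 64L), kernel = 3L, fc = 128L,
                         classes = wisdm_activities(), seed = 1L) {
  stopifnot(inherits(pooling, "pooling_spec"), length(input_shape) == 2L,
            kernel %% 2L == 1L, length(filters) == 2L)
  H1 <- pooled_len(input_shape[1], pooling); W1 <- pooled_len(input_shape[2], pooling)
  if (H1 < 1L || W1 < 1L) stop("input_shape incompatible with pooling layer 1")
  H2 <- pooled_len(H1, pooling); W2 <- pooled_len(W1, pooling)
  if (H2 < 1L || W2 < 1L) stop("input_shape incompatible with pooling layer 2")
  flat <- filters[2] * H2 * W2
  n_classes <- length(classes)
  params <- withr::with_seed(derive_seed(seed, 13L), list(
    W1 = he_init(filters[1], 3L * kernel * kernel),
    b1 = numeric(filters[1]),
    W2 = he_init(filters[2], filters[1] * kernel * kernel),
    b2 = numeric(filters[2]),
    Wf = he_init(fc, flat),
    bf = numeric(fc),
    Wo = he_init(n_classes, fc),
    bo = numeric(n_classes)
  ))
  structure(list(arch = "2d", input_shape = as.integer(input_shape),
                 pooling = pooling, filters = as.integer(filters),
                 kernel = as.integer(kernel), fc = as.integer(fc),
                 classes = classes, n_classes = n_classes,
                 shapes = list(H2 = H2, W2 = W2, flat = flat),
                 params = params, trained = FALSE, history = NULL,
                 seed = as.integer(seed)),
            class = "har_cnn")
}

pooled_len <- function(L, spec) as.integer((L - spec$size) %/% spec$stride + 1L)

he_init <- function(rows, fan_in) {
  matrix(rnorm(rows * fan_in, sd = sqrt(2 / fan_in)), rows, fan_in)
}

#' @export
print.har_cnn <- function(x, ...) {
  cat("<har_cnn> ", x$arch, " path, pooling=", x$pooling$method,
      ", filters=", paste(x$filters, collapse = "/"),
      ", fc=", x$fc, ", classes=", x$n_classes,
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

# Forward pass; returns probabilities plus caches for backprop.
cnn_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  if (model$arch == "1d") {
    c1 <- conv1d_forward(X, p$W1, p$b1)
    a1 <- relu(c1$out)
    p1 <- pool1d_layer_forward(a1, model$pooling)
    c2 <- conv1d_forward(p1$out, p$W2, p$b2)
    a2 <- relu(c2$out)
    p2 <- pool1d_layer_forward(a2, model$pooling)
  } else {
    c1 <- conv2d_forward(X, p$W1, p$b1, model$kernel)
    a1 <- relu(c1$out)
    p1 <- pool2d_layer_forward(a1, model$pooling)
    c2 <- conv2d_forward(p1$out, p$W2, p$b2, model$kernel)
    a2 <- relu(c2$out)
    p2 <- pool2d_layer_forward(a2, model$pooling)
  }
  B <- tail(dim(X), 1)
  flat <- matrix(p2$out, model$shapes$flat, B)
  f1 <- p$Wf %*% flat + p$bf
  af <- relu(f1)
  logits <- p$Wo %*% af + p$bo
  probs <- softmax_cols(logits)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
                      flat = flat, f1 = f1, af = af)
  }
  out
}

# Backward pass for class-weighted cross-entropy; y_idx are 1-based class
# indices, w per-sample weights (already looked up per class).
cnn_backward <- function(model, fw, y_idx, w) {
  p <- model$params
  cache <- fw$cache
  B <- length(y_idx)
  onehot <- matrix(0, model$n_classes, B)
  onehot[cbind(y_idx, seq_len(B))] <- 1
  wsum <- sum(w)
  dlogits <- (fw$probs - onehot) * rep(w / wsum, each = model$n_classes)
  dWo <- dlogits %*% t(cache$af)
  dbo <- rowSums(dlogits)
  daf <- crossprod(p$Wo, dlogits)
  df1 <- daf * (cache$f1 > 0)
  dWf <- df1 %*% t(cache$flat)
  dbf <- rowSums(df1)
  dflat <- crossprod(p$Wf, df1)
  dp2 <- array(dflat, dim = dim(cache$p2$out))
  if (model$arch == "1d") {
    da2 <- pool1d_layer_backward(dp2, cache$p2$cache)
    dc2 <- da2 * (cache$c2$out > 0)
    g2 <- conv1d_backward(dc2, p$W2, cache$c2$cache)
    da1 <- pool1d_layer_backward(g2$dX, cache$p1$cache)
    dc1 <- da1 * (cache$c1$out > 0)
    g1 <- conv1d_backward(dc1, p$W1, cache$c1$cache)
  } else {
    da2 <- pool2d_layer_backward(dp2, cache$p2$cache)
    dc2 <- da2 * (cache$c2$out > 0)
    g2 <- conv2d_backward(dc2, p$W2, cache$c2$cache)
    da1 <- pool2d_layer_backward(g2$dX, cache$p1$cache)
    dc1 <- da1 * (cache$c1$out > 0)
    g1 <- conv2d_backward(dc1, p$W1, cache$c1$cache)
  }
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wf = dWf, bf = dbf, Wo = dWo, bo = dbo)
}

#' Training configuration
#'
#' Adam optimizer settings of the reference training protocol: learning rate
#' 0.001, batch size 64, 10 epochs, class-weighted cross-entropy loss. All
#' stochastic elements of a run (shuffling order) are keyed to `seed`.
#'
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of full passes over the training data.
#' @param seed Integer seed for shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 64L, epochs = 10L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Coerce model input to the tensor layout expected by the architecture and
# return list(X, y). y may be NULL for prediction.
coerce_cnn_input <- function(model, x, y = NULL) {
  if (inherits(x, "har_windows")) {
    if (is.null(y)) y <- x$label
    x <- x$values
  }
  d <- dim(x)
  if (model$arch == "1d") {
    if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
    d <- dim(x)
    if (length(d) != 3L || d[1] != 3L || d[2] != model$input_len) {
      stop("expected a 3 x ", model$input_len, " x B array for the 1d path")
    }
  } else {
    if (length(d) == 3L) x <- array(x, dim = c(d, 1L))
    d <- dim(x)
    if (length(d) != 4L || d[1] != 3L || d[2] != model$input_shape[1] ||
        d[3] != model$input_shape[2]) {
      stop("expected a 3 x ", model$input_shape[1], " x ", model$input_shape[2],
           " x B array for the 2d path")
    }
  }
  if (!is.null(y)) {
    y <- factor(as.character(y), levels = model$classes)
    if (anyNA(y)) stop("labels outside the model's class set")
  }
  list(X = x, y = y)
}

#' Train a reference CNN
#'
#' Runs exactly `config$epochs` passes of mini-batch Adam on the
#' class-weighted cross-entropy loss. Per-epoch training loss and accuracy
#' (and validation accuracy, when a validation set is given) are recorded in
#' the returned model's `history`. Identical seeds yield identical histories
#' on the same platform (pure R forward/backward, no threading
#' nondeterminism).
#'
#' @param model An untrained or trained `har_cnn`.
#' @param x Training inputs: a normalized `har_windows` object (1d path) or
#'   a `3 x rows x cols x n` image array (2d path).
#' @param y Labels (factor/character); taken from `x$label` when `x` is a
#'   `har_windows` object.
#' @param weights Optional named per-class weights as from [class_weights()];
#'   `NULL` trains unweighted.
#' @param config A [train_config()].
#' @param val_x,val_y Optional validation inputs/labels for per-epoch
#'   held-out accuracy.
#' @return The fitted `har_cnn`, with `history` (data.frame: epoch, loss,
#'   train_acc, val_acc).
#' @export
train_cnn <- function(model, x, y = NULL, weights = NULL,
                      config = train_config(), val_x = NULL, val_y = NULL) {
  stopifnot(inherits(model, "har_cnn"), inherits(config, "train_config"))
  inp <- coerce_cnn_input(model, x, y)
  X <- inp$X; yf <- inp$y
  if (is.null(yf)) stop("training labels are required")
  n <- length(yf)
  if (n == 0L) stop("empty training split")
  missing_cls <- setdiff(model$classes, as.character(unique(yf)))
  if (length(missing_cls) > 0L) {
    stop("class(es) absent from training data: ", paste(missing_cls, collapse = ", "))
  }
  wmap <- rep(1, model$n_classes); names(wmap) <- model$classes
  if (!is.null(weights)) wmap[names(weights)] <- weights
  y_idx <- as.integer(yf)
  w_all <- wmap[y_idx]
  has_val <- !is.null(val_x)
  if (has_val) {
    vinp <- coerce_cnn_input(model, val_x, val_y)
    if (is.null(vinp$y)) stop("val_y is required with val_x")
  }
  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  withr::with_seed(derive_seed(config$seed, 17L), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_w <- 0; ep_correct <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        Xb <- index_last(X, idx)
        yb <- y_idx[idx]; wb <- w_all[idx]
        fw <- cnn_forward(model, Xb, keep_cache = TRUE)
        pb <- pmax(fw$probs[cbind(yb, seq_along(yb))], 1e-12)
        ep_loss <- ep_loss + sum(-wb * log(pb))
        ep_w <- ep_w + sum(wb)
        ep_correct <- ep_correct + sum(max.col(t(fw$probs)) == yb)
        grads <- cnn_backward(model, fw, yb, wb)
        upd <- adam_step(model$params, grads, state, lr = config$lr)
        model$params <- upd$params
        state <- upd$state
      }
      val_acc <- NA_real_
      if (has_val) {
        vp <- cnn_forward(model, vinp$X)$probs
        val_acc <- mean(max.col(t(vp)) == as.integer(vinp$y))
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / ep_w,
                                     train_acc = ep_correct / n,
                                     val_acc = val_acc))
      if (config$verbose) {
        message(sprintf("epoch %d/%d loss=%.4f acc=%.3f%s", ep, config$epochs,
                        ep_loss / ep_w, ep_correct / n,
                        if (has_val) sprintf(" val=%.3f", val_acc) else ""))
      }
    }
  })
  model$trained <- TRUE
  model$history <- hist
  model
}

index_last <- function(X, idx) {
  d <- length(dim(X))
  if (d == 3L) X[, , idx, drop = FALSE] else X[, , , idx, drop = FALSE]
}

#' Predict with a reference CNN
#'
#' @param object A fitted `har_cnn`.
#' @param x Inputs (`har_windows` or array matching the build-time shape).
#' @param type `"class"` for hard labels, `"prob"` for the class-probability
#'   matrix (rows sum to 1).
#' @param ... Unused.
#' @return A factor of labels, or an `n x n_classes` probability matrix.
#' @export
predict.har_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  inp <- coerce_cnn_input(object, x)
  probs <- t(cnn_forward(object, inp$X)$probs)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' Stratified train/validation/test split of windows
#'
#' Splits windows into three disjoint sets with the given proportions,
#' stratified by label (default) so every class appears in every split, or
#' grouped by user (`by = "user"`) for a subject-wise protocol in which all
#' windows of a user land in the same split.
#'
#' @param windows A `har_windows` object.
#' @param props Numeric vector of three proportions summing to 1.
#' @param seed Integer seed.
#' @param by `"window"` (stratified by label) or `"user"`.
#' @return Named list of `har_windows`: `train`, `validation`, `test`.
#' @export
split_windows <- function(windows, props = c(0.7, 0.15, 0.15), seed = 1L,
                          by = c("window", "user")) {
  by <- match.arg(by)
  stopifnot(length(props) == 3L, abs(sum(props) - 1) < 1e-8)
  n <- n_windows(windows)
  assign_split <- function(m) {
    k1 <- round(props[1] * m); k2 <- round(props[2] * m)
    rep(c(1L, 2L, 3L), c(k1, k2, m - k1 - k2))
  }
  grp <- withr::with_seed(derive_seed(seed, 19L), {
    g <- integer(n)
    if (by == "window") {
      for (lv in levels(windows$label)) {
        idx <- which(windows$label == lv)
        if (length(idx) == 0L) next
        g[idx] <- sample(assign_split(length(idx)))
      }
    } else {
      users <- unique(windows$user)
      ug <- sample(assign_split(length(users)))
      g <- ug[match(windows$user, users)]
    }
    g
  })
  list(train = windows[grp == 1L],
       validation = windows[grp == 2L],
       test = windows[grp == 3L])
}
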