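# Internal neural-network layer primitives for the reference CNNs.
#
# All heavy lifting is expressed as BLAS matrix products via an
# im2col/col2im scheme; tensors are base R arrays with the channel dimension
# first and the batch dimension last. Convolutions use 'same' zero padding
# (odd kernels), stride 1. The pooling layers dispatch to the same
# vectorized reducers as pool_1d()/pool_2d() so the CNN pooling is
# bit-identical to the signal-level transforms.

relu <- function(x) pmax(x, 0)

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# --- 1D convolution ---------------------------------------------------------

conv1d_forward <- function(X, W, b) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  K <- ncol(W) / C
  p <- (K - 1) %/% 2
  Xpad <- array(0, dim = c(C, L + 2 * p, B))
  Xpad[, (p + 1):(p + L), ] <- X
  Xcol <- matrix(0, C * K, L * B)
  for (k in seq_len(K)) {
    Xcol[((k - 1) * C + 1):(k * C), ] <- matrix(Xpad[, k:(k + L - 1), , drop = FALSE], C, L * B)
  }
  Y <- W %*% Xcol + b
  list(out = array(Y, dim = c(nrow(W), L, B)),
       cache = list(Xcol = Xcol, C = C, L = L, B = B, K = K, p = p))
}

conv1d_backward <- function(dY, W, cache) {
  C <- cache$C; L <- cache$L; B <- cache$B; K <- cache$K; p <- cache$p
  dYm <- matrix(dY, nrow(W), L * B)
  dW <- dYm %*% t(cache$Xcol)
  db <- rowSums(dYm)
  dXcol <- crossprod(W, dYm)
  dXpad <- array(0, dim = c(C, L + 2 * p, B))
  for (k in seq_len(K)) {
    dXpad[, k:(k + L - 1), ] <- dXpad[, k:(k + L - 1), , drop = FALSE] +
      array(dXcol[((k - 1) * C + 1):(k * C), ], dim = c(C, L, B))
  }
  list(dX = dXpad[, (p + 1):(p + L), , drop = FALSE], dW = dW, db = db)
}

# --- 2D convolution (square odd kernel, 'same' padding) ---------------------

conv2d_forward <- function(X, W, b, K) {
  d <- dim(X); C <- d[1]; H <- d[2]; Wd <- d[3]; B <- d[4]
  p <- (K - 1) %/% 2
  Xpad <- array(0, dim = c(C, H + 2 * p, Wd + 2 * p, B))
  Xpad[, (p + 1):(p + H), (p + 1):(p + Wd), ] <- X
  n <- H * Wd * B
  Xcol <- matrix(0, C * K * K, n)
  blk <- 0L
  for (kj in seq_len(K)) {
    for (ki in seq_len(K)) {
      Xcol[(blk * C + 1):((blk + 1) * C), ] <-
        matrix(Xpad[, ki:(ki + H - 1), kj:(kj + Wd - 1), , drop = FALSE], C, n)
      blk <- blk + 1L
    }
  }
  Y <- W %*% Xcol + b
  list(out = array(Y, dim = c(nrow(W), H, Wd, B)),
       cache = list(Xcol = Xcol, C = C, H = H, Wd = Wd, B = B, K = K, p = p))
}

conv2d_backward <- function(dY, W, cache) {
  C <- cache$C; H <- cache$H; Wd <- cache$Wd; B <- cache$B
  K <- cache$K; p <- cache$p
  n <- H * Wd * B
  dYm <- matrix(dY, nrow(W), n)
  dW <- dYm %*% t(cache$Xcol)
  db <- rowSums(dYm)
  dXcol <- crossprod(W, dYm)
  dXpad <- array(0, dim = c(C, H + 2 * p, Wd + 2 * p, B))
  blk <- 0L
  for (kj in seq_len(K)) {
    for (ki in seq_len(K)) {
      dXpad[, ki:(ki + H - 1), kj:(kj + Wd - 1), ] <-
        dXpad[, ki:(ki + H - 1), kj:(kj + Wd - 1), , drop = FALSE] +
        array(dXcol[(blk * C + 1):((blk + 1) * C), ], dim = c(C, H, Wd, B))
      blk <- blk + 1L
    }
  }
  list(dX = dXpad[, (p + 1):(p + H), (p + 1):(p + Wd), , drop = FALSE],
       dW = dW, db = db)
}

# --- pooling layers ---------------------------------------------------------

# Per-window gradient coefficients for each reducer, given the size x n
# window matrix. For max/ecp the (sub)gradient flows to the first argmax /
# argmin occurrence; cmv additionally spreads the -d(sigma)/dx_i term
# (x_i - mean) / (n * sigma) over all positions, with the sigma = 0 case
# (flat window) contributing nothing from the variation term.
pool_grad_coefs <- function(wm, method, alpha) {
  s <- nrow(wm); n <- ncol(wm)
  G <- matrix(0, s, n)
  cols <- seq_len(n)
  if (method == "average") {
    G[] <- 1 / s
  } else if (method == "max") {
    am <- max.col(t(wm), ties.method = "first")
    G[cbind(am, cols)] <- 1
  } else if (method == "ecp") {
    am <- max.col(t(wm), ties.method = "first")
    ai <- max.col(t(-wm), ties.method = "first")
    rows <- asplit(wm, 1)
    r <- Reduce(pmax, rows) - Reduce(pmin, rows)
    i1 <- cbind(am, cols); i2 <- cbind(ai, cols)
    G[i1] <- G[i1] + 0.5 - 2 * alpha * r
    G[i2] <- G[i2] + 0.5 + 2 * alpha * r
  } else if (method == "cmv") {
    am <- max.col(t(wm), ties.method = "first")
    ai <- max.col(t(-wm), ties.method = "first")
    mu <- colMeans(wm)
    sig <- sqrt(pmax(colMeans(wm^2) - mu^2, 0))
    denom <- s * sig
    centered <- sweep(wm, 2, mu)
    G <- -sweep(centered, 2, ifelse(denom > 0, denom, Inf), "/")
    i1 <- cbind(am, cols); i2 <- cbind(ai, cols)
    G[i1] <- G[i1] + 0.5
    G[i2] <- G[i2] + 0.5
  } else {
    stop("unknown pooling method: ", method)
  }
  G
}

pool1d_layer_forward <- function(A, spec) {
  d <- dim(A); F_ <- d[1]; L <- d[2]; B <- d[3]
  s <- spec$size; st <- spec$stride
  Lo <- (L - s) %/% st + 1L
  n <- F_ * Lo * B
  wm <- matrix(0, s, n)
  pos <- st * (seq_len(Lo) - 1L)
  for (k in seq_len(s)) {
    wm[k, ] <- as.vector(A[, k + pos, , drop = FALSE])
  }
  out <- array(reduce_windows(wm, spec$method, spec$alpha), dim = c(F_, Lo, B))
  list(out = out, cache = list(wm = wm, dims = d, Lo = Lo, pos = pos, spec = spec))
}

pool1d_layer_backward <- function(dY, cache) {
  spec <- cache$spec
  d <- cache$dims; F_ <- d[1]; B <- d[3]
  Lo <- cache$Lo
  G <- pool_grad_coefs(cache$wm, spec$method, spec$alpha)
  dYv <- as.vector(dY)
  dA <- array(0, dim = d)
  for (k in seq_len(spec$size)) {
    dA[, k + cache$pos, ] <- dA[, k + cache$pos, , drop = FALSE] +
      array(G[k, ] * dYv, dim = c(F_, Lo, B))
  }
  dA
}

pool2d_layer_forward <- function(A, spec) {
  d <- dim(A); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  s <- spec$size; st <- spec$stride
  Ho <- (H - s) %/% st + 1L
  Wo <- (W - s) %/% st + 1L
  n <- C * Ho * Wo * B
  wm <- matrix(0, s * s, n)
  r0 <- st * (seq_len(Ho) - 1L)
  c0 <- st * (seq_len(Wo) - 1L)
  k <- 0L
  for (kj in seq_len(s)) {
    for (ki in seq_len(s)) {
      k <- k + 1L
      wm[k, ] <- as.vector(A[, ki + r0, kj + c0, , drop = FALSE])
    }
  }
  out <- array(reduce_windows(wm, spec$method, spec$alpha), dim = c(C, Ho, Wo, B))
  list(out = out, cache = list(wm = wm, dims = d, Ho = Ho, Wo = Wo,
                               r0 = r0, c0 = c0, spec = spec))
}

pool2d_layer_backward <- function(dY, cache) {
  spec <- cache$spec
  d <- cache$dims; C <- d[1]; B <- d[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  G <- pool_grad_coefs(cache$wm, spec$method, spec$alpha)
  dYv <- as.vector(dY)
  dA <- array(0, dim = d)
  k <- 0L
  for (kj in seq_len(spec$size)) {
    for (ki in seq_len(spec$size)) {
      k <- k + 1L
      dA[, ki + cache$r0, kj + cache$c0, ] <-
        dA[, ki + cache$r0, kj + cache$c0, , drop = FALSE] +
        array(G[k, ] * dYv, dim = c(C, Ho, Wo, B))
    }
  }
  dA
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
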