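# Shared fixtures and independent oracles, all built in code.

# A tiny hand-written record set: two users, mixed activities.
tiny_records <- function() {
  data.frame(
    user = c(1L, 1L, 1L, 2L, 2L),
    activity = factor(c("Walking", "Walking", "Jogging", "Sitting", "Sitting"),
                      levels = wisdm_activities()),
    timestamp = c(0, 50, 100, 0, 50),
    x = c(0.1, 0.2, 0.3, 1.1, 1.2),
    y = c(9.8, 9.7, 9.6, 4.9, 4.8),
    z = c(0.2, 0.1, 0.0, 8.3, 8.2)
  )
}

# Records with a single user, one activity, deterministic ramp values.
ramp_records <- function(n, user = 1L, activity = "Walking") {
  data.frame(
    user = user,
    activity = factor(activity, levels = wisdm_activities()),
    timestamp = (seq_len(n) - 1) * 50,
    x = seq_len(n) / n, y = rev(seq_len(n)) / n, z = cos(seq_len(n) / 5)
  )
}

# Naive per-window loop oracles for the pooling transforms; deliberately
# independent of the vectorized implementation.
scalar_reduce <- function(v, method, alpha = 0.5) {
  switch(method,
         max = max(v),
         average = mean(v),
         ecp = ecp(v, alpha),
         cmv = cmv(v))
}

naive_pool_1d <- function(x, spec) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  L <- ncol(x)
  n_out <- floor((L - spec$size) / spec$stride) + 1
  out <- matrix(NA_real_, nrow(x), n_out)
  for (ci in seq_len(nrow(x))) {
    for (j in seq_len(n_out)) {
      i0 <- (j - 1) * spec$stride + 1
      out[ci, j] <- scalar_reduce(x[ci, i0:(i0 + spec$size - 1)],
                                  spec$method, spec$alpha)
    }
  }
  out
}

naive_pool_2d <- function(a, spec) {
  C <- dim(a)[1]; H <- dim(a)[2]; W <- dim(a)[3]
  Ho <- floor((H - spec$size) / spec$stride) + 1
  Wo <- floor((W - spec$size) / spec$stride) + 1
  out <- array(NA_real_, c(C, Ho, Wo))
  for (ci in seq_len(C)) {
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        r <- (i - 1) * spec$stride + 1
        cc <- (j - 1) * spec$stride + 1
        patch <- a[ci, r:(r + spec$size - 1), cc:(cc + spec$size - 1)]
        out[ci, i, j] <- scalar_reduce(as.vector(patch), spec$method, spec$alpha)
      }
    }
  }
  out
}

# Small normalized window set for benchmark-style tests.
small_windows <- function(n = 10, seed = 42, activities = NULL) {
  synthetic_normalized_windows(n, seed = seed, activities = activities)
}
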