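test_that("layer chain shapes match the flatten arithmetic", {
  m1 <- build_cnn_1d(100)
  expect_equal(m1$shapes$L2, 25L)
  expect_equal(m1$shapes$flat, 1600L)
  m2 <- build_cnn_2d(c(10, 10))
  expect_equal(c(m2$shapes$H2, m2$shapes$W2), c(2L, 2L))
  expect_equal(m2$shapes$flat, 256L)
  expect_error(build_cnn_1d(3), "incompatible")
  # pooling method never changes shapes
  for (meth in c("max", "average", "cmv")) {
    mm <- build_cnn_1d(100, pooling_spec(meth, 2))
    expect_equal(mm$shapes, m1$shapes)
  }
})

test_that("forward pass emits softmax probabilities for any batch", {
  m <- build_cnn_1d(40, filters = c(4, 8), fc = 16, classes = c("A", "B", "C"))
  X <- array(runif(3 * 40 * 5), c(3, 40, 5))
  p <- predict(m, X, type = "prob")
  expect_equal(dim(p), c(5L, 3L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  lab <- predict(m, X)
  expect_equal(as.integer(lab), apply(p, 1, which.max))  # argmax consistency
  one <- predict(m, array(X[, , 1], c(3, 40, 1)))
  expect_length(one, 1L)
  expect_error(predict(m, array(0, c(3, 39, 2))), "expected")
})

test_that("CNN pooling layers agree with pool_1d/pool_2d exactly", {
  withr::with_seed(21, {
    for (meth in c("max", "average", "ecp", "cmv")) {
      spec <- pooling_spec(meth, 2)
      A <- array(runif(4 * 12 * 3), c(4, 12, 3))
      out <- harpool:::pool1d_layer_forward(A, spec)$out
      for (b in 1:3) {
        expect_identical(out[, , b], pool_1d(A[, , b], spec))
      }
      A2 <- array(runif(2 * 6 * 8 * 3), c(2, 6, 8, 3))
      out2 <- harpool:::pool2d_layer_forward(A2, spec)$out
      for (b in 1:3) {
        expect_identical(out2[, , , b], pool_2d(A2[, , , b], spec))
      }
    }
  })
})

test_that("pooling layer gradients match central finite differences", {
  withr::with_seed(22, {
    for (meth in c("ecp", "cmv", "max", "average")) {
      spec <- pooling_spec(meth, 2)
      A <- array(runif(2 * 8 * 2), c(2, 8, 2))
      fw <- harpool:::pool1d_layer_forward(A, spec)
      dY <- array(rnorm(length(fw$out)), dim = dim(fw$out))
      dA <- harpool:::pool1d_layer_backward(dY, fw$cache)
      eps <- 1e-6
      for (i in sample(length(A), 10)) {
        Ap <- A; Ap[i] <- Ap[i] + eps
        Am <- A; Am[i] <- Am[i] - eps
        num <- sum(dY * (harpool:::pool1d_layer_forward(Ap, spec)$out -
                         harpool:::pool1d_layer_forward(Am, spec)$out)) / (2 * eps)
        expect_equal(dA[i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("full-model gradients match finite differences (both paths)", {
  withr::with_seed(23, {
    for (arch in c("1d", "2d")) {
      if (arch == "1d") {
        m <- build_cnn_1d(12, pooling_spec("ecp", 2), filters = c(2, 3),
                          fc = 4, classes = c("A", "B"), seed = 5)
        X <- array(runif(3 * 12 * 4), c(3, 12, 4))
      } else {
        m <- build_cnn_2d(c(6, 6), pooling_spec("cmv", 2), filters = c(2, 3),
                          fc = 4, classes = c("A", "B"), seed = 5)
        X <- array(runif(3 * 6 * 6 * 4), c(3, 6, 6, 4))
      }
      y <- c(1L, 2L, 1L, 2L); w <- c(1, 2, 1, 1.5)
      fw <- harpool:::cnn_forward(m, X, keep_cache = TRUE)
      g <- harpool:::cnn_backward(m, fw, y, w)
      lossfn <- function(params) {
        m2 <- m; m2$params <- params
        pr <- harpool:::cnn_forward(m2, X)$probs
        sum(-w * log(pmax(pr[cbind(y, 1:4)], 1e-12))) / sum(w)
      }
      eps <- 1e-6
      for (nm in c("W1", "W2", "Wf", "Wo", "b1", "bf")) {
        for (i in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
          pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
          pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
          num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
          expect_equal(g[[nm]][i], num, tolerance = 1e-4)
        }
      }
    }
  })
})

test_that("training learns a separable toy problem and logs history", {
  withr::with_seed(24, {
    n <- 120
    X <- array(0, c(3, 20, n))
    y <- rep(c("A", "B"), each = n / 2)
    for (i in seq_len(n)) {
      base <- if (y[i] == "A") 0.3 else 0.7
      X[, , i] <- matrix(base + rnorm(60, 0, 0.05), 3, 20)
    }
    X <- pmin(pmax(X, 0), 1)
    m <- build_cnn_1d(20, pooling_spec("average", 2), filters = c(4, 8),
                      fc = 8, classes = c("A", "B"), seed = 1)
    cfg <- train_config(epochs = 10, batch_size = 8, seed = 1)
    fit <- train_cnn(m, X, y, config = cfg)
    expect_equal(nrow(fit$history), 10L)
    expect_gte(fit$history$train_acc[10], 0.99)
    # same seed reproduces the history exactly
    fit2 <- train_cnn(m, X, y, config = cfg)
    expect_equal(fit$history, fit2$history, tolerance = 1e-12)
    expect_error(train_cnn(m, X, rep("A", n),
                           config = train_config(epochs = 1)), "absent")
  })
})

test_that("class weighting lifts minority recall on imbalanced toy data", {
  recalls <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    withr::with_seed(30 + s, {
      n_maj <- 108; n_min <- 12; n <- n_maj + n_min
      X <- array(0, c(3, 20, n))
      y <- c(rep("A", n_maj), rep("B", n_min))
      for (i in seq_len(n)) {
        base <- if (y[i] == "A") 0.45 else 0.55
        X[, , i] <- matrix(base + rnorm(60, 0, 0.08), 3, 20)
      }
      X <- pmin(pmax(X, 0), 1)
      m <- build_cnn_1d(20, pooling_spec("average", 2), filters = c(2, 4),
                        fc = 4, classes = c("A", "B"), seed = s)
      cfg <- train_config(epochs = 6, batch_size = 8, seed = s)
      fit_u <- train_cnn(m, X, y, config = cfg)
      fit_w <- train_cnn(m, X, y, weights = class_weights(y), config = cfg)
      rec <- function(fit) {
        pred <- predict(fit, X)
        mean(pred[y == "B"] == "B")
      }
      recalls[s, ] <- c(rec(fit_u), rec(fit_w))
    })
  }
  expect_gte(mean(recalls[, 2]), mean(recalls[, 1]))
})

test_that("stratified and user-wise splits partition the windows", {
  w <- synthetic_normalized_windows(60, seed = 31)
  sp <- split_windows(w, seed = 2)
  expect_equal(n_windows(sp$train) + n_windows(sp$validation) + n_windows(sp$test),
               n_windows(w))
  expect_true(all(levels(w$label) %in% as.character(sp$train$label)))
  rec <- generate_stream(config = generator_config(n_users = 5,
                                                   seconds_per_activity = 10,
                                                   seed = 4))
  wu <- segment_windows(rec, 100, 100)
  spu <- split_windows(wu, seed = 3, by = "user")
  users_by_split <- lapply(spu, function(s) unique(s$user))
  expect_equal(length(Reduce(intersect, users_by_split[lengths(users_by_split) > 0])), 0L)
})
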