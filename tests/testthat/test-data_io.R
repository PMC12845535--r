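test_that("reader parses plain and semicolon dialects, sorted by time", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,Walking,100,0.1,9.8,0.2",
               "1,Walking,0,0.0,9.9,0.1;",
               "1,Jogging,50,0.5,9.5,0.3;;"), f)
  rec <- read_wisdm_csv(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$timestamp, c(0, 50, 100))
  expect_equal(as.character(rec$activity), c("Walking", "Jogging", "Walking"))
  expect_equal(attr(rec, "skipped"), 0L)
})

test_that("invalid rows are skipped and counted; blank lines tolerated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,Walking,0,0.1,9.8,0.2",
               "",
               "1,Running,50,0.1,9.8,0.2",   # unknown label
               "1,Walking,100,abc,9.8,0.2",  # bad numeric
               "1,Walking,150,0.2",          # too few fields
               "1,Walking,200,0.3,9.7,0.1;"), f)
  expect_message(rec <- read_wisdm_csv(f), "skipped 3")
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "skipped"), 3L)
})

test_that("reader errors on missing or empty files", {
  expect_error(read_wisdm_csv(file.path(tempdir(), "nope-xyz.csv")), "not found")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_wisdm_csv(f), "no rows")
  writeLines("1,Running,0,1,2,3", f)
  expect_error(read_wisdm_csv(f, quiet = TRUE), "no valid rows")
})

test_that("write/read round-trip preserves every field", {
  rec <- generate_stream(config = generator_config(n_users = 2,
                                                   seconds_per_activity = 5,
                                                   seed = 3))
  for (dialect in c("plain", "semicolon")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_wisdm_csv(rec, f, dialect = dialect)
    back <- read_wisdm_csv(f, quiet = TRUE)
    expect_equal(back$user, rec$user)
    expect_equal(as.character(back$activity), as.character(rec$activity))
    expect_equal(back$timestamp, rec$timestamp)
    expect_equal(back$x, rec$x, tolerance = 1e-12)
    expect_equal(back$y, rec$y, tolerance = 1e-12)
    expect_equal(back$z, rec$z, tolerance = 1e-12)
  }
})

test_that("window counts follow the floor formula", {
  expect_equal(n_windows(segment_windows(ramp_records(600), 200, 200)), 3L)
  expect_equal(n_windows(segment_windows(ramp_records(400), 100, 50)), 7L)
  expect_equal(n_windows(segment_windows(ramp_records(99), 100, 50)), 0L)
})

test_that("window counts match naive enumeration on random triples", {
  withr::with_seed(11, {
    for (i in 1:200) {
      N <- sample(2:500, 1)
      wl <- sample(2:min(N + 50, 250), 1)
      st <- sample(seq_len(wl), 1)
      # oracle: count start positions by brute force
      expected <- if (N < wl) 0L else sum((seq(1, N, by = st) + wl - 1) <= N)
      got <- n_windows(segment_windows(ramp_records(N), wl, st))
      expect_equal(got, expected, info = sprintf("N=%d wl=%d st=%d", N, wl, st))
    }
  })
})

test_that("majority labeling works and ties break to the earliest label", {
  rec <- ramp_records(100)
  rec$activity[61:100] <- "Jogging"   # 60 Walking vs 40 Jogging
  w <- segment_windows(rec, 100, 100)
  expect_equal(as.character(w$label), "Walking")
  rec$activity[] <- "Jogging"; rec$activity[51:100] <- "Walking"  # 50/50 tie
  w <- segment_windows(rec, 100, 100)
  expect_equal(as.character(w$label), "Jogging")  # Jogging occurs first
})

test_that("segmentation never crosses user boundaries and tiles disjointly", {
  rec <- rbind(ramp_records(150, user = 1L), ramp_records(130, user = 2L))
  w <- segment_windows(rec, 100, 100)
  expect_equal(n_windows(w), 2L)  # one per user, tails dropped
  expect_equal(sort(unique(w$user)), c(1L, 2L))
  # stride = window_len: starts spaced exactly window_len apart per user
  w2 <- segment_windows(ramp_records(500), 100, 100)
  expect_equal(w2$start, c(1L, 101L, 201L, 301L, 401L))
})

test_that("min-max fit finds global extrema and rejects constant axes", {
  rec <- ramp_records(200)
  rec$x <- seq(-20, 20, length.out = 200)
  w <- segment_windows(rec, 100, 100)
  p <- fit_minmax(w)
  expect_equal(unname(p$min["x"]), -20, tolerance = 1e-9)
  expect_equal(unname(p$max["x"]), 20, tolerance = 1e-9)
  # union over windows
  rec2 <- ramp_records(200)
  rec2$x <- c(seq(0, 5, length.out = 100), seq(3, 9, length.out = 100))
  w2 <- segment_windows(rec2, 100, 100)
  p2 <- fit_minmax(w2)
  expect_equal(unname(p2$min["x"]), 0)
  expect_equal(unname(p2$max["x"]), 9)
  rec3 <- ramp_records(100)
  rec3$z <- 0.5  # constant axis
  expect_error(fit_minmax(segment_windows(rec3, 100, 100)), "z")
})

test_that("apply_minmax maps endpoints, midpoints, and clamps", {
  rec <- ramp_records(200)
  rec$x <- seq(-20, 20, length.out = 200)
  w <- segment_windows(rec, 100, 100)
  p <- fit_minmax(w)
  wn <- apply_minmax(w, p)
  expect_gte(min(wn$values), 0)
  expect_lte(max(wn$values), 1)
  # v = 0 on axis spanning [-20, 20] maps to 0.5
  i0 <- which.min(abs(w$values[1, , 1] - 0))
  expect_equal(wn$values[1, i0, 1], 0.5, tolerance = 0.02)
  # out-of-range test value clamps to 1 with clip, errors without
  w$values[1, 1, 1] <- 25
  expect_equal(apply_minmax(w, p)$values[1, 1, 1], 1)
  expect_error(apply_minmax(w, p, clip = FALSE), "outside")
})

test_that("clipped normalization bounds hold for arbitrary inputs", {
  withr::with_seed(5, {
    rec <- ramp_records(300)
    rec$x <- rnorm(300, 0, 50); rec$y <- rt(300, 2); rec$z <- runif(300, -9, 9)
    w <- segment_windows(rec, 100, 50)
    p <- fit_minmax(w)
    w$values <- w$values * 3 + 1  # values far outside the fitted range
    wn <- apply_minmax(w, p)
    expect_gte(min(wn$values), 0)
    expect_lte(max(wn$values), 1)
  })
})

test_that("class weights follow N / (K * n_c)", {
  expect_equal(class_weights(c("A", "A", "B", "B")), c(A = 1, B = 1))
  w <- class_weights(c("A", "A", "A", "B"))
  expect_equal(w, c(A = 4 / 6, B = 4 / 2))
  expect_equal(class_weights(c("A", "A")), c(A = 1))
  expect_error(class_weights(character(0)), "empty")
  # mean over classes of n_c * w_c is N / K
  labs <- c(rep("A", 7), rep("B", 2), rep("C", 3))
  w3 <- class_weights(labs)
  expect_equal(mean(table(labs) * w3[names(table(labs))]), 12 / 3)
})

test_that("windows round-trip through the columnar container", {
  w <- small_windows(4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(w, f)
  back <- read_windows_csv(f)
  expect_equal(back$values, w$values, tolerance = 1e-12)
  expect_equal(as.character(back$label), as.character(w$label))
  expect_equal(back$user, w$user)
  expect_equal(back$start, w$start)
})
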