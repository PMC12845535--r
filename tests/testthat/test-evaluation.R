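test_that("confusion matrix counts and validates labels", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         classes = c("A", "B"))
  expect_equal(unname(cm), rbind(c(1L, 1L), c(0L, 2L)))
  expect_equal(sum(cm), 4L)
  expect_equal(unname(rowSums(cm)), c(2L, 2L))
  perfect <- confusion_matrix(c("A", "B"), c("A", "B"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion_matrix("A", "C", classes = c("A", "B")), "unknown")
  pct <- confusion_percent(cm)
  expect_equal(unname(rowSums(pct)), c(100, 100))
})

test_that("fbeta follows the formula and its limits", {
  expect_equal(fbeta(0.7, 0.7, 2), 0.7)              # P = R fixed point
  expect_equal(fbeta(1, 0.5, 2), 5 * 0.5 / 4.5)
  expect_equal(fbeta(0.6, 0.8, 1), 2 * 0.6 * 0.8 / 1.4)  # harmonic mean
  expect_equal(fbeta(0, 0, 1), 0)
  expect_error(fbeta(0.5, 0.5, -1), "non-negative")
  # monotone in both arguments
  withr::with_seed(14, {
    p <- sort(runif(10)); r <- runif(1)
    expect_true(all(diff(fbeta(p, r, 0.5)) >= 0))
    expect_true(all(diff(fbeta(r, p, 2)) >= 0))
  })
})

test_that("classification report reproduces hand-computed metrics", {
  true <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  rep_ <- classification_report(true, pred, classes = c("A", "B"))
  a <- rep_$per_class[rep_$per_class$class == "A", ]
  expect_equal(a$precision, 1)
  expect_equal(a$recall, 0.5)
  expect_equal(a$f1, 2 / 3)
  expect_equal(rep_$accuracy, 0.75)
  # micro accuracy = trace / total
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / sum(rep_$confusion))
  # equal supports: weighted equals macro
  expect_equal(rep_$weighted[["f1"]], rep_$macro[["f1"]], tolerance = 1e-12)
})

test_that("perfect classifier scores 1 everywhere and aggregates exactly", {
  withr::with_seed(15, {
    true <- sample(c("A", "B", "C"), 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    prob <- matrix(0.001, 60, 3, dimnames = list(NULL, c("A", "B", "C")))
    prob[cbind(seq_len(60), match(true, c("A", "B", "C")))] <- 0.998
    rep_ <- classification_report(true, true, prob, classes = c("A", "B", "C"))
    expect_equal(rep_$accuracy, 1)
    expect_true(all(rep_$per_class[, c("precision", "recall", "f1", "auc")] == 1))
    # weighted aggregates equal support-weighted means of per-class columns
    wt <- rep_$per_class$support / sum(rep_$per_class$support)
    expect_equal(rep_$weighted[["precision"]],
                 sum(rep_$per_class$precision * wt), tolerance = 1e-12)
    expect_equal(rep_$weighted[["f1"]],
                 sum(rep_$per_class$f1 * wt), tolerance = 1e-12)
  })
})

test_that("AUC is ranked correctly and undefined classes are excluded", {
  true <- c("A", "A", "B", "B")
  prob <- cbind(A = c(0.9, 0.6, 0.4, 0.1), B = c(0.1, 0.4, 0.6, 0.9))
  rep_ <- classification_report(true, c("A", "A", "B", "B"), prob,
                                classes = c("A", "B"))
  expect_equal(rep_$per_class$auc, c(1, 1))
  # a class with zero support: NA sentinel + warning, excluded from macro
  warns <- character()
  rep2 <- withCallingHandlers(
    classification_report(true, c("A", "A", "B", "B"), cbind(prob, C = 0),
                          classes = c("A", "B", "C")),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("undefined", warns)))
  expect_true(is.na(rep2$per_class$auc[3]))
  expect_equal(rep2$macro[["auc"]], 1)
})

test_that("zero-division metrics report 0 with a warning", {
  expect_warning(rep_ <- classification_report(c("A", "A"), c("B", "B"),
                                               classes = c("A", "B")),
                 "zero denominator")
  expect_equal(rep_$per_class$recall, c(0, 0))
})

test_that("degradation deltas are zero for identical reports, positive = worse", {
  true <- c("A", "A", "B", "B"); pred <- c("A", "B", "B", "B")
  r <- classification_report(true, pred, classes = c("A", "B"))
  d0 <- degradation_analysis(r, r)
  expect_true(all(d0$per_class$delta_acc == 0))
  expect_equal(d0$accuracy_drop, 0)
  worse <- suppressWarnings(
    classification_report(true, c("B", "B", "B", "B"), classes = c("A", "B")))
  d1 <- suppressWarnings(degradation_analysis(r, worse))
  expect_gte(d1$per_class$delta_acc[1], 0)   # A degraded -> positive delta
  expect_equal(d1$per_class$top_confusion[1], "B")
  r3 <- classification_report(c("A", "C"), c("A", "C"), classes = c("A", "C"))
  expect_error(degradation_analysis(r, r3), "mismatch")
})

test_that("artifact analysis with zero perturbation equals clean error rates", {
  w <- synthetic_normalized_windows(30, seed = 16)
  # stub predictor: deterministic rule, independent of any trained model
  rule <- function(win) {
    means <- apply(win$values[3, , , drop = FALSE], 3, mean)
    factor(ifelse(means > 0.5, "Sitting", "Walking"),
           levels = wisdm_activities())
  }
  tab <- artifact_fp_analysis(rule, w, w)
  expect_equal(nrow(tab), length(unique(as.character(w$label))))
  expect_equal(tab$fp_rate, 1 - tab$clean_accuracy, tolerance = 1e-12)
  expect_error(artifact_fp_analysis(rule, w[integer(0)], w[integer(0)]), "empty")
  expect_error(artifact_fp_analysis(rule, w, w[1:3]), "matched")
})
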