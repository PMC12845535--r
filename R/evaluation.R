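#' Confusion matrix
#'
#' Entry `(i, j)` counts items of true class `i` predicted as class `j`;
#' row sums equal the class supports.
#'
#' @param true,predicted Label vectors (factor/character).
#' @param classes Class order; defaults to the union of levels. Labels
#'   outside `classes` are an error.
#' @return A `K x K` integer matrix with dimnames `(true, predicted)`.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(true, levels = classes), factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' F-beta score from precision and recall
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, defined as 0 when both
#' precision and recall are 0. `beta = 1` is the harmonic mean (F1);
#' `beta = 2` weights recall, `beta = 0.5` weights precision.
#'
#' @param precision,recall Values in `[0, 1]` (vectorized).
#' @param beta Non-negative weight.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' fbeta(1, 0.5, 2)  # 5 * 0.5 / 4.5
fbeta <- function(precision, recall, beta = 1) {
  if (beta < 0) stop("beta must be non-negative")
  stopifnot(all(precision >= 0 & precision <= 1), all(recall >= 0 & recall <= 1))
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

#' Multi-class classification report
#'
#' Per-class precision, recall, F1, F2, F0.5 and support, plus one-vs-rest
#' ROC AUC when a probability matrix is supplied; aggregated as macro
#' (unweighted mean) and weighted (support-weighted mean) averages, plus
#' micro accuracy. Per-class metrics with an empty denominator are reported
#' as 0 with a warning. A class with zero support has an undefined AUC: it
#' is reported as `NA` and excluded from the macro AUC with a warning.
#'
#' @param true,predicted Label vectors.
#' @param prob Optional `n x K` probability matrix (rows sum to 1, columns
#'   named or ordered by `classes`) for ROC AUC.
#' @param classes Class order; defaults to the union of observed labels.
#' @return An object of class `har_report`: list with `per_class`
#'   (data.frame), `accuracy`, `macro`, `weighted` (named vectors),
#'   `confusion` (count matrix), and `classes`.
#' @export
classification_report <- function(true, predicted, prob = NULL, classes = NULL) {
  cm <- confusion_matrix(true, predicted, classes)
  classes <- rownames(cm)
  K <- length(classes)
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  zero_div <- FALSE
  safe_div <- function(a, b) {
    out <- ifelse(b == 0, 0, a / b)
    if (any(b == 0)) zero_div <<- TRUE
    out
  }
  precision <- safe_div(tp, pred_tot)
  recall <- safe_div(tp, support)
  if (zero_div) warning("zero denominator in precision/recall; reported as 0")
  f1 <- fbeta(precision, recall, 1)
  f2 <- fbeta(precision, recall, 2)
  f05 <- fbeta(precision, recall, 0.5)
  auc <- rep(NA_real_, K)
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    if (!is.null(colnames(prob))) prob <- prob[, classes, drop = FALSE]
    if (ncol(prob) != K) stop("prob must have one column per class")
    truth <- as.character(true)
    for (k in seq_len(K)) {
      is_k <- as.integer(truth == classes[k])
      if (sum(is_k) == 0L || sum(is_k) == length(is_k)) next  # undefined
      auc[k] <- as.numeric(pROC::auc(pROC::roc(
        response = is_k, predictor = prob[, k], quiet = TRUE,
        direction = "<", levels = c(0, 1))))
    }
    if (anyNA(auc)) {
      warning("ROC AUC undefined for class(es) without both outcomes: ",
              paste(classes[is.na(auc)], collapse = ", "),
              "; excluded from macro average")
    }
  }
  per_class <- data.frame(class = classes, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          f2 = as.numeric(f2), f0.5 = as.numeric(f05),
                          auc = auc, support = as.integer(support))
  wt <- support / sum(support)
  agg <- function(v, w = NULL) {
    if (is.null(w)) mean(v, na.rm = TRUE) else sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)])
  }
  macro <- c(precision = mean(precision), recall = mean(recall), f1 = mean(f1),
             f2 = mean(f2), f0.5 = mean(f05), auc = agg(auc))
  weighted <- c(precision = sum(precision * wt), recall = sum(recall * wt),
                f1 = sum(f1 * wt), f2 = sum(f2 * wt), f0.5 = sum(f05 * wt),
                auc = agg(auc, wt))
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / sum(cm),
                 macro = macro, weighted = weighted,
                 confusion = cm, classes = classes),
            class = "har_report")
}

#' @export
print.har_report <- function(x, digits = 3, ...) {
  cat("<har_report> accuracy =", round(x$accuracy, digits), "\n")
  df <- x$per_class
  df[, 2:7] <- round(df[, 2:7], digits)
  print(df, row.names = FALSE)
  cat("macro:    ", paste(names(x$macro), round(x$macro, digits), sep = "=",
                          collapse = " "), "\n")
  cat("weighted: ", paste(names(x$weighted), round(x$weighted, digits), sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}

#' Row-normalized confusion percentages
#'
#' @param cm Count confusion matrix.
#' @return Matrix of row percentages (each row sums to 100 when its support
#'   is nonzero).
#' @export
confusion_percent <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  100 * cm / rs
}

#' Degradation between a clean and a noisy evaluation
#'
#' Computes per-class deltas (clean minus noisy, so positive means
#' degradation) for per-class accuracy (recall) and F1, plus the overall
#' accuracy drop, and identifies each class's top off-diagonal confusion
#' target in the noisy confusion matrix.
#'
#' @param report_clean,report_noisy `har_report` objects over the same class
#'   order.
#' @return A list with `per_class` (data.frame: class, acc_clean, acc_noisy,
#'   delta_acc, f1_clean, f1_noisy, delta_f1, top_confusion) and
#'   `accuracy_drop`.
#' @export
degradation_analysis <- function(report_clean, report_noisy) {
  stopifnot(inherits(report_clean, "har_report"), inherits(report_noisy, "har_report"))
  if (!identical(report_clean$classes, report_noisy$classes)) {
    stop("mismatched class sets")
  }
  classes <- report_clean$classes
  cmn <- report_noisy$confusion
  top_conf <- vapply(seq_along(classes), function(i) {
    row <- cmn[i, ]; row[i] <- -1L
    if (max(row) <= 0L) NA_character_ else classes[which.max(row)]
  }, character(1))
  per_class <- data.frame(
    class = classes,
    acc_clean = report_clean$per_class$recall,
    acc_noisy = report_noisy$per_class$recall,
    delta_acc = report_clean$per_class$recall - report_noisy$per_class$recall,
    f1_clean = report_clean$per_class$f1,
    f1_noisy = report_noisy$per_class$f1,
    delta_f1 = report_clean$per_class$f1 - report_noisy$per_class$f1,
    top_confusion = top_conf
  )
  list(per_class = per_class,
       accuracy_drop = report_clean$accuracy - report_noisy$accuracy)
}

#' False-positive analysis under motion artifacts
#'
#' Evaluates a fitted model on matched clean and artifact-corrupted windows
#' (same windows, same order) and reports, per true class: accuracy on the
#' clean windows, accuracy under artifacts, the false-positive rate (the
#' fraction of artifact windows predicted as a different class), and the
#' most frequent misclassification target under artifacts.
#'
#' @param model A fitted `har_cnn` (1d path) or a function mapping a
#'   `har_windows` object to predicted labels.
#' @param clean_windows Normalized `har_windows` with labels.
#' @param artifact_windows The same windows after
#'   [add_motion_artifacts()]/[corrupt_windows()] and re-normalization.
#' @return A data.frame with one row per class present in the labels.
#' @export
artifact_fp_analysis <- function(model, clean_windows, artifact_windows) {
  stopifnot(inherits(clean_windows, "har_windows"),
            inherits(artifact_windows, "har_windows"))
  if (n_windows(clean_windows) == 0L) stop("empty input")
  if (n_windows(clean_windows) != n_windows(artifact_windows)) {
    stop("clean and artifact window sets must be matched")
  }
  pred_fun <- if (inherits(model, "har_cnn")) {
    function(w) predict(model, w)
  } else {
    model
  }
  pc <- as.character(pred_fun(clean_windows))
  pa <- as.character(pred_fun(artifact_windows))
  truth <- as.character(clean_windows$label)
  present <- unique(truth)
  classes <- intersect(levels(clean_windows$label), present)
  rows <- lapply(classes, function(cl) {
    i <- truth == cl
    wrong <- pa[i][pa[i] != cl]
    data.frame(
      class = cl,
      clean_accuracy = mean(pc[i] == cl),
      artifact_accuracy = mean(pa[i] == cl),
      fp_rate = mean(pa[i] != cl),
      top_misclassification = if (length(wrong) == 0L) NA_character_
        else names(which.max(table(wrong))),
      n = sum(i)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
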