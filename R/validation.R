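#' Hold-out split of a report corpus
#'
#' Partitions the rows of a corpus into disjoint training and test sets by
#' a seeded uniform shuffle (no stratification). The test size is
#' `round(n * test_fraction)`.
#'
#' @param records a data.frame (or list) of at least 2 records.
#' @param test_fraction proportion in (0, 1).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with elements `train` and `test`.
#' @export
holdout_split <- function(records, test_fraction, seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 2L) stop("need at least 2 records to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n) {
    stop("degenerate split: test size would be ", n_test, " of ", n)
  }
  with_seed(seed, {
    idx <- sample.int(n)
    test_idx <- sort(idx[seq_len(n_test)])
    train_idx <- sort(idx[-seq_len(n_test)])
    if (is.data.frame(records)) {
      list(train = records[train_idx, , drop = FALSE],
           test = records[test_idx, , drop = FALSE])
    } else {
      list(train = records[train_idx], test = records[test_idx])
    }
  })
}

check_labels_probs <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  check_prob(probabilities, "probabilities")
}

#' Threshold classification metrics
#'
#' Confusion counts and the derived class metrics at a probability
#' threshold: prediction is positive iff `probability >= threshold`.
#' Accuracy = (TP+TN)/N, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall. Precision or recall with a
#' zero denominator is reported as `NA` (absent) rather than 0, and F1 is
#' then `NA` too.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities, same length.
#' @param threshold classification threshold (default 0.5).
#' @return list with `confusion` (named tp/fp/fn/tn), `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  check_labels_probs(labels, probabilities)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1); fp <- sum(pred == 1L & labels == 0)
  fn <- sum(pred == 0L & labels == 1); tn <- sum(pred == 0L & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the binary
#' outcomes: `(1/N) * sum((p_i - y_i)^2)`. Lower is better calibrated; 0
#' iff predictions equal the labels exactly.
#'
#' @inheritParams classification_metrics
#' @return value in \[0, 1\].
#' @export
brier_score <- function(labels, probabilities) {
  check_labels_probs(labels, probabilities)
  mean((probabilities - labels)^2)
}

#' ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a uniformly random positive instance is scored above a
#' uniformly random negative one, with ties counted 1/2 — computed via the
#' rank-sum identity, equal to the trapezoidal area under the ROC curve.
#'
#' @inheritParams classification_metrics
#' @return proportion in \[0, 1\].
#' @export
roc_auc <- function(labels, probabilities) {
  check_labels_probs(labels, probabilities)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC AUC requires both classes to be present")
  }
  r <- rank(probabilities)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Reliability curve
#'
#' Bins predictions into `n_bins` equal-width bins on \[0, 1\] (right-open
#' except the last) and reports, per non-empty bin, the mean predicted
#' probability, the observed positive fraction and the bin count. A
#' well-calibrated model tracks the identity line.
#'
#' @inheritParams classification_metrics
#' @param n_bins number of bins (default 10).
#' @return data.frame with columns `mean_predicted`, `observed_fraction`,
#'   `count`; counts sum to `length(labels)`.
#' @export
reliability_curve <- function(labels, probabilities, n_bins = 10L) {
  check_labels_probs(labels, probabilities)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  bin <- pmin(floor(probabilities * n_bins), n_bins - 1L) + 1L
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(mean_predicted = mean(probabilities[sel]),
               observed_fraction = mean(labels[sel]),
               count = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Least-squares slope of a reliability curve
#'
#' Slope of the unweighted least-squares line through the (mean predicted,
#' observed fraction) points; 1 indicates perfect calibration.
#'
#' @param curve a data.frame from [reliability_curve()].
#' @return slope (numeric scalar; `NA` with fewer than 2 bins).
#' @export
reliability_slope <- function(curve) {
  if (nrow(curve) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(observed_fraction ~ mean_predicted,
                               data = curve))[2L])
}

#' Full hold-out validation report
#'
#' Evaluates predicted probabilities against held-out labels: confusion
#' metrics at the classification threshold, Brier score, ROC AUC and the
#' reliability curve.
#'
#' @inheritParams classification_metrics
#' @param n_bins reliability-curve bins.
#' @return object of class `validation_report`.
#' @export
validation_report <- function(labels, probabilities, threshold = 0.5,
                              n_bins = 10L) {
  cm <- classification_metrics(labels, probabilities, threshold)
  structure(c(cm,
              list(brier = brier_score(labels, probabilities),
                   roc_auc = roc_auc(labels, probabilities),
                   reliability = reliability_curve(labels, probabilities,
                                                   n_bins),
                   threshold = threshold,
                   n = length(labels))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f%%", 100 * v))
  cat("Hold-out validation (n =", x$n, ", threshold =", x$threshold, ")\n")
  cat("  accuracy ", pct(x$accuracy), "  precision ", pct(x$precision),
      "  recall ", pct(x$recall), "  F1 ", pct(x$f1), "\n", sep = "")
  cat("  Brier score ", pct(x$brier), "  ROC AUC ", pct(x$roc_auc),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  x <- unclass(report)
  x$confusion <- as.list(x$confusion)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                          dataframe = "columns", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Plot a reliability curve
#'
#' Observed positive fraction against mean predicted probability per bin,
#' with the identity line of perfect calibration.
#'
#' @param curve data.frame from [reliability_curve()].
#' @param main plot title.
#' @return `NULL`, invisibly (draws on the active device).
#' @export
plot_reliability_curve <- function(curve, main = "Reliability curve") {
  plot(curve$mean_predicted, curve$observed_fraction, type = "b", pch = 19,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Mean predicted probability",
       ylab = "Fraction of positives", main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(NULL)
}
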