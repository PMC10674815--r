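#' Confusion counts for binary QC labels
#'
#' Tabulates true/false positives and negatives with `'good'` as the positive
#' class (a "positive" is a print accepted as good; sensitivity therefore
#' measures recognition of true good prints).
#'
#' @param actual,predicted label vectors (`'good'`/`'bad'`), equal length.
#' @param positive the positive class (default `'good'`).
#' @return an object of class `qc_confusion`: list with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(actual, predicted, positive = "good") {
  a <- .as_label(actual)
  p <- .as_label(predicted)
  if (length(a) != length(p))
    stop("actual and predicted must have equal length", call. = FALSE)
  pos <- positive
  neg <- setdiff(c("good", "bad"), pos)
  structure(list(
    tp = sum(a == pos & p == pos),
    fp = sum(a == neg & p == pos),
    tn = sum(a == neg & p == neg),
    fn = sum(a == pos & p == neg)
  ), class = "qc_confusion")
}

#' @export
print.qc_confusion <- function(x, ...) {
  cat(sprintf("<qc_confusion tp=%d fp=%d tn=%d fn=%d>\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

.ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " is undefined (zero denominator)", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / (TP + FP + TN + FN)`, sensitivity `TP / (TP + FN)`
#' and specificity `TN / (TN + FP)`. A zero denominator yields `NA` with a
#' warning -- an explicitly undefined result, never silently 0.
#'
#' @param counts a [confusion_counts] object.
#' @return a real in `[0, 1]`, or `NA` when undefined.
#' @export
accuracy <- function(counts) {
  with(counts, .ratio_or_na(tp + tn, tp + fp + tn + fn, "accuracy"))
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  with(counts, .ratio_or_na(tp, tp + fn, "sensitivity"))
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  with(counts, .ratio_or_na(tn, tn + fp, "specificity"))
}

#' Per-instance class probabilities with actual labels
#'
#' @param probs `n x 2` row-stochastic matrix in fixed class order
#'   (`bad`, `good`), or a vector of `'good'`-class probabilities.
#' @param actuals `n` labels.
#' @return an object of class `prob_predictions`.
#' @export
prob_predictions <- function(probs, actuals) {
  if (is.null(dim(probs))) probs <- cbind(bad = 1 - probs, good = probs)
  probs <- as.matrix(probs)
  if (ncol(probs) != 2L) stop("probs must have 2 columns (bad, good)", call. = FALSE)
  if (is.null(colnames(probs))) colnames(probs) <- c("bad", "good")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("probability rows must sum to 1", call. = FALSE)
  actuals <- .as_label(actuals)
  if (length(actuals) != nrow(probs))
    stop("probs and actuals must have equal length", call. = FALSE)
  structure(list(probs = probs, actuals = actuals), class = "prob_predictions")
}

#' Brier score
#'
#' Mean squared difference between the probability assigned to the positive
#' (`'good'`) class and the 0/1 indicator of `'good'`:
#' `(1/N) * sum((p_good - actual)^2)`. For two classes this single-class
#' scoring is equivalent (up to the conventional factor) to summing both
#' class halves and keeps the score in `[0, 1]`: 0 for a perfect degenerate
#' predictor, 0.25 for the constant-0.5 predictor, scores below 0.25
#' indicating acceptable calibration.
#'
#' @param p a [prob_predictions], or a vector of `'good'`-class
#'   probabilities.
#' @param actuals labels; ignored when `p` is a `prob_predictions`.
#' @return the Brier score in `[0, 1]`.
#' @export
brier_score <- function(p, actuals = NULL) {
  if (!inherits(p, "prob_predictions")) p <- prob_predictions(p, actuals)
  ind <- as.numeric(p$actuals == "good")
  mean((p$probs[, "good"] - ind)^2)
}

#' Area under the ROC curve (rank-based)
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' positive instance receives a strictly higher score than a randomly chosen
#' negative one, with ties credited 0.5. Equivalent to trapezoidal
#' integration of the empirical ROC curve; 1 is a perfect test, 0.5 a
#' worthless one. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher means more `'good'`-like).
#' @param actuals labels.
#' @return AUROC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
auroc <- function(scores, actuals) {
  a <- .as_label(actuals)
  if (length(scores) != length(a))
    stop("scores and actuals must have equal length", call. = FALSE)
  npos <- sum(a == "good")
  nneg <- sum(a == "bad")
  if (npos == 0 || nneg == 0) {
    warning("AUROC is undefined with a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[a == "good"]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Trapezoidal integration of the empirical ROC curve; independent
# cross-check of the rank-based AUROC used in the test suite.
.auroc_trapezoid <- function(scores, actuals) {
  a <- .as_label(actuals)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(thr))
  npos <- sum(a == "good"); nneg <- sum(a == "bad")
  for (i in seq_along(thr)) {
    call_good <- scores >= thr[i]
    tpr[i] <- sum(call_good & a == "good") / npos
    fpr[i] <- sum(call_good & a == "bad") / nneg
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Most-confident statistic
#'
#' Per-instance maximum of the two class probabilities -- the probability the
#' model assigns to whichever class it predicts. For two classes the value is
#' bounded below by 0.5 (maximal uncertainty) and above by 1 (full
#' confidence).
#'
#' @param p a [prob_predictions] or an `n x 2` row-stochastic matrix.
#' @return numeric vector of values in `[0.5, 1]`.
#' @export
most_confident <- function(p) {
  m <- if (inherits(p, "prob_predictions")) p$probs else as.matrix(p)
  pmax(m[, 1], m[, 2])
}

#' Evaluate a fitted model on a test matrix
#'
#' One prediction pass yields the full metrics report: confusion counts,
#' accuracy, sensitivity, specificity, rank-based AUROC (scored on the
#' `'good'`-class probability), Brier score and the most-confident profile.
#'
#' @param model a `qc_model`.
#' @param x test features (`feature_matrix` or plain matrix).
#' @param y test labels; taken from `x` when it is a `feature_matrix`.
#' @return an object of class `qc_metrics`.
#' @export
evaluate_model <- function(model, x, y = NULL) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$values
  }
  y <- .as_label(y)
  probs <- predict(model, x, type = "prob")
  pg <- probs[, "good"]
  pred <- factor(ifelse(pg > 0.5, "good", "bad"), levels = c("bad", "good"))
  counts <- confusion_counts(y, pred)
  pp <- prob_predictions(probs, y)
  structure(list(
    counts = counts,
    accuracy = accuracy(counts),
    sensitivity = sensitivity(counts),
    specificity = specificity(counts),
    auroc = auroc(pg, y),
    brier = brier_score(pp),
    confidence_profile = most_confident(pp),
    n = length(y),
    technique = model$technique,
    tuned = model$tuned
  ), class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf(
    "<qc_metrics %s%s n=%d acc=%.3f sens=%.3f spec=%.3f auroc=%.3f brier=%.3f>\n",
    x$technique %||% "", if (isTRUE(x$tuned)) " (tuned)" else "",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$auroc, x$brier))
  invisible(x)
}

#' Flatten a metrics report to a one-row data.frame
#'
#' @param report a `qc_metrics`.
#' @param ... extra columns (e.g. form, size, color space) recycled to one row.
#' @return a data.frame suitable for row-binding into results grids.
#' @export
metrics_row <- function(report, ...) {
  data.frame(...,
             n = report$n,
             tp = report$counts$tp, fp = report$counts$fp,
             tn = report$counts$tn, fn = report$counts$fn,
             accuracy = report$accuracy,
             sensitivity = report$sensitivity,
             specificity = report$specificity,
             auroc = report$auroc,
             brier = report$brier,
             stringsAsFactors = FALSE)
}
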