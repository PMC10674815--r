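#' Default hyperparameter grids
#'
#' Candidate grids for the seven techniques, evaluated in declared row order
#' by [qc_train()] (ties in cross-validated accuracy go to the earlier row).
#' `max_depth = 0` means unlimited. The random-forest grid deliberately
#' includes tree counts below 10, since small forests are competitive on this
#' task.
#'
#' @param technique one of `"DT"`, `"RF"`, `"GB"`, `"MLP"`, `"SVM"`, `"kNN"`,
#'   `"LR"`.
#' @return a data.frame of candidate hyperparameter rows.
#' @export
default_grid <- function(technique) {
  switch(technique,
    DT  = expand.grid(max_depth = c(3, 5, 10, 0), min_leaf = c(1, 5)),
    RF  = expand.grid(num_trees = c(5, 10, 50, 100), max_depth = c(3, 5, 10, 0)),
    GB  = expand.grid(num_trees = c(50, 100), learning_rate = c(0.1, 0.3),
                      max_depth = c(2, 3)),
    MLP = data.frame(hidden = c(64, 256)),
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 1e-4)),
    kNN = data.frame(k = c(1, 3, 5, 11)),
    LR  = data.frame(lambda = c(0.01, 0.1, 1)),
    stop("unknown technique: ", technique, call. = FALSE)
  )
}

# Defaults used when tuned = FALSE ("untuned" = library defaults, no search).
.untuned_params <- function(technique) {
  switch(technique,
    DT  = list(max_depth = 30, min_leaf = 7, cp = 0.01),
    RF  = list(num_trees = 500, max_depth = 0),
    GB  = list(num_trees = 100, learning_rate = 0.3, max_depth = 6),
    MLP = list(hidden = 100),
    SVM = list(cost = 1, gamma = NA),
    kNN = list(k = 5),
    LR  = list(lambda = 0.01)
  )
}

#' Resource limits for model fitting
#'
#' Very wide feature matrices make some learners impractically expensive;
#' fits that would exceed these limits return a structured
#' "exceeded limits" model rather than crashing, so sweeps can report the
#' cell as incomplete. Logistic regression is capped by feature count and the
#' multilayer perceptron by total weight count.
#'
#' @param lr_max_features maximum feature dimension for `"LR"`.
#' @param mlp_max_weights maximum network weight count for `"MLP"`.
#' @return a list of class `qc_limits`.
#' @export
qc_limits <- function(lr_max_features = 20000, mlp_max_weights = 4e6) {
  structure(list(lr_max_features = lr_max_features,
                 mlp_max_weights = mlp_max_weights),
            class = "qc_limits")
}

.as_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  y <- tolower(as.character(y))
  if (!all(y %in% c("good", "bad")))
    stop("labels must be 'good'/'bad'", call. = FALSE)
  factor(y, levels = c("bad", "good"))
}

# stratified fold assignment, deterministic under seed
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.exceeds_limits <- function(technique, params, d, limits) {
  if (technique == "LR" && d > limits$lr_max_features)
    return(sprintf("LR with %d features exceeds the %d-feature limit",
                   d, as.integer(limits$lr_max_features)))
  if (technique == "MLP") {
    nw <- (d + 1) * params$hidden + (params$hidden + 1)
    if (nw > limits$mlp_max_weights)
      return(sprintf("MLP with %d weights exceeds the %d-weight limit",
                     nw, as.integer(limits$mlp_max_weights)))
  }
  NULL
}

# Fit one technique with fixed hyperparameters. Returns an object that
# .predict_good() can score.
.fit_one <- function(technique, params, x, y, seed) {
  set.seed(seed)
  d <- ncol(x)
  switch(technique,
    DT = {
      df <- data.frame(y = y)
      df$x <- x
      ctrl <- rpart::rpart.control(
        maxdepth = if (params$max_depth == 0) 30 else params$max_depth,
        minbucket = params$min_leaf %||% 1,
        minsplit = max(2, 2 * (params$min_leaf %||% 1)),
        cp = params$cp %||% 0, xval = 0,
        maxsurrogate = 0, maxcompete = 0, usesurrogate = 0)
      rpart::rpart(y ~ x, data = df, method = "class", control = ctrl)
    },
    RF = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      seed = seed, num.threads = 1),
    GB = xgboost::xgboost(
      x, y, objective = "binary:logistic",
      nrounds = params$num_trees,
      learning_rate = params$learning_rate,
      max_depth = params$max_depth,
      nthreads = 1, seed = seed, verbosity = 0),
    MLP = nnet::nnet(
      x = x, y = as.numeric(y == "good"), size = params$hidden,
      entropy = TRUE, maxit = 150, decay = 1e-4, trace = FALSE,
      MaxNWts = (d + 1) * params$hidden + params$hidden + 10),
    SVM = {
      gam <- params$gamma
      if (is.na(gam)) {
        v <- stats::var(as.vector(x))
        gam <- if (v > 0) 1 / (d * v) else 1 / d
      }
      e1071::svm(x = x, y = y, kernel = "radial", cost = params$cost,
                 gamma = gam, probability = TRUE, scale = FALSE)
    },
    kNN = list(x = x, y = y, k = params$k),
    LR = glmnet::glmnet(
      x = x, y = as.integer(y == "good"), family = "binomial",
      alpha = 0, lambda = params$lambda, standardize = FALSE, maxit = 1e5)
  )
}

# probability of class 'good' for each row of x
.predict_good <- function(technique, fit, x) {
  switch(technique,
    DT = {
      nd <- data.frame(row.names = seq_len(nrow(x)))
      nd$x <- x
      p <- stats::predict(fit, newdata = nd, type = "prob")
      as.numeric(p[, "good"])
    },
    RF = {
      p <- stats::predict(fit, data = x, num.threads = 1)$predictions
      as.numeric(p[, "good"])
    },
    GB = as.numeric(stats::predict(fit, x)),
    MLP = as.numeric(stats::predict(fit, x)),
    SVM = {
      p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(p[, "good"])
    },
    kNN = {
      tr <- fit$x
      k <- min(fit$k, nrow(tr))
      # squared Euclidean distances; nearest neighbours with ties broken by
      # training-row index for determinism
      tr2 <- rowSums(tr^2)
      pg <- numeric(nrow(x))
      step <- max(1L, floor(2e7 / nrow(tr)))
      for (s in seq(1L, nrow(x), by = step)) {
        e <- min(s + step - 1L, nrow(x))
        xb <- x[s:e, , drop = FALSE]
        d2 <- outer(rowSums(xb^2), tr2, "+") - 2 * tcrossprod(xb, tr)
        for (r in seq_len(nrow(xb))) {
          nn <- order(d2[r, ], seq_len(ncol(d2)))[seq_len(k)]
          pg[s + r - 1L] <- mean(fit$y[nn] == "good")
        }
      }
      pg
    },
    LR = as.numeric(stats::predict(fit, x, type = "response"))
  )
}

#' Fit a quality-control classifier
#'
#' The single fitting interface for all seven techniques: decision tree
#' (`DT`), random forest (`RF`), gradient-boosted trees (`GB`), multilayer
#' perceptron (`MLP`), support-vector machine with RBF kernel (`SVM`),
#' k-nearest neighbours (`kNN`) and L2-penalized logistic regression (`LR`).
#' With `tuned = TRUE` every grid row is scored by stratified k-fold
#' cross-validated accuracy and the best row (ties: first in declared order)
#' is refit on the full training matrix. With `tuned = FALSE` the technique's
#' library defaults are used with no search.
#'
#' The positive class is `'good'` throughout; predicted probabilities are
#' returned in fixed class order (`bad`, `good`) and the label rule is argmax
#' with ties resolved to `'bad'` (the conservative call for quality control).
#'
#' @param x numeric feature matrix (`n x d`), or a `feature_matrix` from
#'   [flatten_images()] (in which case `y` is taken from it).
#' @param y labels (`'good'`/`'bad'`); ignored when `x` is a
#'   `feature_matrix`.
#' @param technique learner name, see above.
#' @param tuned run the cross-validated grid search?
#' @param grid candidate data.frame; `NULL` uses [default_grid()].
#' @param cv_folds number of stratified folds (>= 2).
#' @param seed seed governing fold assignment and any fit randomness.
#' @param limits a [qc_limits]; fits beyond them return an
#'   `"exceeded limits"` model (`status` field) instead of failing.
#' @return an object of class `qc_model` with fields `technique`, `tuned`,
#'   `best_params`, `cv_results`, `fit`, `status`, `d` and `seed`.
#' @export
qc_train <- function(x, y = NULL,
                     technique = c("DT", "RF", "GB", "MLP", "SVM", "kNN", "LR"),
                     tuned = TRUE, grid = NULL, cv_folds = 5L, seed = 1L,
                     limits = qc_limits()) {
  technique <- match.arg(technique)
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$values
  }
  if (is.null(y)) stop("`y` is required when `x` is a plain matrix", call. = FALSE)
  y <- .as_label(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("px", seq_len(ncol(x)))
  d <- ncol(x)

  mk <- function(fit, params, cv_results, status = "ok", reason = NULL) {
    structure(list(technique = technique, tuned = tuned,
                   best_params = params, cv_results = cv_results,
                   fit = fit, status = status, reason = reason,
                   classes = c("bad", "good"), d = d,
                   feature_names = colnames(x), seed = as.integer(seed)),
              class = "qc_model")
  }

  if (!tuned) {
    params <- .untuned_params(technique)
    reason <- .exceeds_limits(technique, params, d, limits)
    if (!is.null(reason)) return(mk(NULL, params, NULL, "exceeded_limits", reason))
    fit <- .fit_one(technique, params, x, y, seed)
    return(mk(fit, params, NULL))
  }

  grid <- grid %||% default_grid(technique)
  if (nrow(grid) < 1L) stop("grid must be non-empty when tuned", call. = FALSE)
  keep <- vapply(seq_len(nrow(grid)), function(i)
    is.null(.exceeds_limits(technique, as.list(grid[i, , drop = FALSE]), d, limits)),
    logical(1))
  if (!any(keep)) {
    p1 <- stats::setNames(lapply(names(grid), function(j) grid[1, j]), names(grid))
    reason <- .exceeds_limits(technique, p1, d, limits)
    return(mk(NULL, p1, NULL, "exceeded_limits", reason))
  }
  grid <- grid[keep, , drop = FALSE]

  k <- min(cv_folds, min(table(y)))
  if (k < 2L) stop("not enough instances per class for cross-validation", call. = FALSE)
  fold <- .stratified_folds(y, k, seed)
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- .fit_one(technique, params, x[tr, , drop = FALSE], y[tr], seed)
      pg <- .predict_good(technique, fit, x[!tr, , drop = FALSE])
      pred <- ifelse(pg > 0.5, "good", "bad")
      acc[f] <- mean(pred == as.character(y[!tr]))
    }
    scores[gi] <- mean(acc)
  }
  best <- which(scores >= max(scores) - 1e-12)[1]
  best_params <- stats::setNames(lapply(names(grid), function(j) grid[best, j]),
                                 names(grid))
  cv_results <- cbind(grid, cv_accuracy = scores)
  fit <- .fit_one(technique, best_params, x, y, seed)
  mk(fit, best_params, cv_results)
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf("<qc_model %s %s status=%s d=%d>\n", x$technique,
              if (x$tuned) "tuned" else "untuned", x$status, x$d))
  if (x$status == "ok" && !is.null(x$best_params))
    cat("  params:", paste(names(x$best_params),
                           unlist(x$best_params), sep = "=", collapse = ", "), "\n")
  if (x$status != "ok") cat("  ", x$reason, "\n")
  invisible(x)
}

#' @export
summary.qc_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_results)) {
    cat("cross-validated grid:\n")
    print(object$cv_results)
  }
  invisible(object)
}

#' Predict from a fitted QC model
#'
#' @param object a `qc_model` from [qc_train()].
#' @param x feature matrix (or `feature_matrix`) with the training dimension.
#' @param type `"prob"` for the `n x 2` row-stochastic probability matrix
#'   (class order `bad`, `good`), `"label"` for the argmax labels with ties
#'   going to `'bad'`.
#' @param ... unused.
#' @return probability matrix or factor of labels.
#' @export
predict.qc_model <- function(object, x, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (object$status != "ok")
    stop("model did not fit (", object$status, "): ", object$reason, call. = FALSE)
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != object$d)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$d, ncol(x)), call. = FALSE)
  colnames(x) <- object$feature_names
  pg <- .predict_good(object$technique, object$fit, x)
  pg <- pmin(pmax(pg, 0), 1)
  if (type == "prob") {
    out <- cbind(bad = 1 - pg, good = pg)
    return(out)
  }
  factor(ifelse(pg > 0.5, "good", "bad"), levels = c("bad", "good"))
}
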