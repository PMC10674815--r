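#' Stress-test configuration
#'
#' @param techniques learners for the stress program (default the tree-based
#'   pair, which consistently performs well at low cost).
#' @param sizes image sizes (square px) to sweep.
#' @param crop_fractions the 4 center-crop fractions of the augmentation.
#' @param n_ood_per_kind OOD images per distractor kind.
#' @param seed root seed.
#' @return a list of class `stress_config`.
#' @export
stress_config <- function(techniques = c("DT", "RF"),
                          sizes = c(25, 50, 125),
                          crop_fractions = c(0.9, 0.8, 0.7, 0.6),
                          n_ood_per_kind = 200L,
                          seed = 1L) {
  if (length(techniques) < 1L) stop("need at least one technique", call. = FALSE)
  if (length(crop_fractions) != 4L) stop("need exactly 4 crop fractions", call. = FALSE)
  structure(list(techniques = techniques, sizes = sizes,
                 crop_fractions = crop_fractions,
                 n_ood_per_kind = as.integer(n_ood_per_kind),
                 seed = as.integer(seed)),
            class = "stress_config")
}

#' Scalability stress test on the 16x-augmented test set
#'
#' The training set is only grayscale-transformed (never augmented, so it
#' keeps its original count); the test set is expanded 16-fold by
#' [augment_test_set()]. One metrics report is produced per technique and
#' image size. Tuned models may be passed in to be reused (keeping the
#' scaling question separate from fit variance); otherwise they are trained
#' here.
#'
#' @param train,test [qc_dataset]s; the test set needs both classes.
#' @param config a [stress_config].
#' @param models optional nested list `models[[technique]][[as.character(size)]]`
#'   of prefit `qc_model`s to reuse.
#' @return list with `grid` (data.frame of metric rows), `reports` (the
#'   `qc_metrics` objects), and `models`.
#' @export
run_scalability <- function(train, test, config = stress_config(), models = NULL) {
  if (length(test) < 2L || length(unique(dataset_labels(test))) < 2L)
    stop("test set needs at least 2 images covering both classes", call. = FALSE)
  train_gray <- qc_dataset(lapply(train$items, to_grayscale),
                           form = train$metadata$form, seed = train$metadata$seed)

  grid <- list(); reports <- list(); fitted <- list()
  for (size in config$sizes) {
    cfg <- preprocess_config(size, "gray", "unit_0_1")
    fm_train <- flatten_images(preprocess_dataset(train_gray, cfg), cfg)
    # Augmented test matrix built one source image at a time (16 views each)
    # so full-resolution test sets never sit in memory 16-fold.
    n_aug <- 16L * length(test)
    vals <- matrix(0, n_aug, size * size)
    labs <- character(n_aug); prov <- character(n_aug)
    k <- 0L
    for (i in seq_along(test$items)) {
      for (img in .augment_one(to_grayscale(test$items[[i]]), i,
                               config$crop_fractions)) {
        k <- k + 1L
        vals[k, ] <- as.vector(t(resize_image(img, size)$pixels)) / 255
        labs[k] <- img$label
        prov[k] <- img$digest
      }
    }
    colnames(vals) <- paste0("px", seq_len(ncol(vals)))
    fm_test <- structure(list(values = vals,
                              labels = factor(labs, levels = c("bad", "good")),
                              defects = NULL, provenance = prov,
                              shape = c(size, size), config = cfg),
                         class = "feature_matrix")
    for (tech in config$techniques) {
      model <- models[[tech]][[as.character(size)]] %||%
        qc_train(fm_train, technique = tech, tuned = TRUE, seed = config$seed)
      rep <- evaluate_model(model, fm_test)
      key <- sprintf("%s_%d", tech, size)
      reports[[key]] <- rep
      fitted[[tech]][[as.character(size)]] <- model
      grid[[key]] <- metrics_row(rep, technique = tech, size = size)
    }
  }
  list(grid = do.call(rbind, grid), reports = reports, models = fitted)
}

#' Out-of-distribution robustness test
#'
#' Feeds distractor images (which depict no dosage form) through the
#' identical preprocessing path as test images and records, per model and
#' kind, the fraction classified `'bad'` -- the OOD accuracy. The aim is that
#' a deployable model never calls a random object `'good'`.
#'
#' @param models list of fitted `qc_model`s (any mix of tuned/untuned).
#' @param form dosage form whose OOD battery to use (see [ood_kinds()]).
#' @param size image size the models were trained at.
#' @param n_per_kind distractors per kind.
#' @param canvas_px OOD canvas side before preprocessing.
#' @param seed root seed for distractor generation.
#' @param kinds OOD kinds to run (default the form's 4-kind battery).
#' @return data.frame with columns technique, tuned, kind, size, n,
#'   ood_accuracy.
#' @export
run_ood <- function(models, form, size, n_per_kind = 200L, canvas_px = 512L,
                    seed = 1L, kinds = ood_kinds(form)) {
  if (length(models) == 0) stop("no models supplied", call. = FALSE)
  cfg <- preprocess_config(size, "gray", "unit_0_1")
  rows <- list()
  std <- function(img) resize_image(if (cfg$color_space == "gray")
    to_grayscale(img) else img, cfg$target_size_px)
  for (kind in kinds) {
    ds <- generate_ood_set(ood_spec(kind, n = n_per_kind,
                                    canvas_px = canvas_px, seed = seed),
                           transform = std)
    fm <- flatten_images(ds, cfg)
    for (mi in seq_along(models)) {
      model <- models[[mi]]
      pred <- predict(model, fm, type = "label")
      rows[[length(rows) + 1L]] <- data.frame(
        technique = model$technique,
        tuned = model$tuned,
        kind = kind,
        size = size,
        n = length(pred),
        ood_accuracy = mean(pred == "bad"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Confidence report: most-confident histogram plus Brier score
#'
#' Bins the per-instance most-confident values into fixed 0.05-wide bins
#' over `[0.5, 1.0]` (the last bin is closed so a fully confident prediction
#' falls in the `[0.95, 1.0]` bin) and attaches the Brier score.
#'
#' @param p a [prob_predictions].
#' @return list of class `confidence_report` with `histogram` (named counts),
#'   `breaks`, and `brier`.
#' @export
confidence_report <- function(p) {
  if (!inherits(p, "prob_predictions"))
    stop("`p` must be a prob_predictions", call. = FALSE)
  mc <- most_confident(p)
  breaks <- seq(0.5, 1, by = 0.05)
  bin <- findInterval(mc, breaks, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  names(counts) <- sprintf("[%.2f,%.2f%s", utils::head(breaks, -1),
                           utils::tail(breaks, -1),
                           c(rep(")", length(breaks) - 2L), "]"))
  structure(list(histogram = counts, breaks = breaks, brier = brier_score(p)),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report n=%d brier=%.3f>\n", sum(x$histogram), x$brier))
  print(x$histogram)
  invisible(x)
}
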