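#' Experiment configuration
#'
#' One configuration object governs the full study sweep. May be built
#' directly or loaded from YAML via [load_config()]; every source of
#' randomness flows from the single root seed.
#'
#' @param forms dosage forms to run.
#' @param sizes image-size sweep (square px).
#' @param color_spaces `"rgb"`, `"gray"` or both.
#' @param techniques learners to run.
#' @param n_train_good,n_train_bad training class counts.
#' @param n_test pseudo-real test-set size (even).
#' @param train_canvas_px,test_canvas_px render canvas sides; the test canvas
#'   defaults to twice the training canvas, giving the severalfold
#'   encoded-file-size gap between the corpora.
#' @param seed root seed.
#' @param out_dir output directory for [qc_run()]/[qc_stress()].
#' @param limits a [qc_limits] applied to every fit in the sweep.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(forms = c("capsule", "tablet", "film"),
                              sizes = c(25, 50, 125, 256, 512),
                              color_spaces = c("rgb", "gray"),
                              techniques = c("LR", "DT", "RF", "GB", "MLP", "SVM", "kNN"),
                              n_train_good = 100L, n_train_bad = 100L,
                              n_test = 200L,
                              train_canvas_px = 512L,
                              test_canvas_px = 2L * train_canvas_px,
                              seed = 1L, out_dir = "results",
                              limits = qc_limits()) {
  stopifnot(length(forms) >= 1, length(sizes) >= 1, length(techniques) >= 1)
  structure(list(forms = forms, sizes = sizes, color_spaces = color_spaces,
                 techniques = techniques,
                 n_train_good = as.integer(n_train_good),
                 n_train_bad = as.integer(n_train_bad),
                 n_test = as.integer(n_test),
                 train_canvas_px = as.integer(train_canvas_px),
                 test_canvas_px = as.integer(test_canvas_px),
                 seed = as.integer(seed), out_dir = out_dir,
                 limits = limits),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file whose keys override the defaults of
#'   [experiment_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(experiment_config, vals)
}

# next free append-only run directory under out_dir
.next_run_dir <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  i <- 1L
  repeat {
    d <- file.path(out_dir, sprintf("run-%03d", i))
    if (!dir.exists(d)) {
      dir.create(d)
      return(d)
    }
    i <- i + 1L
  }
}

.write_provenance <- function(dir, config, extra = list()) {
  prov <- c(list(
    package = "dosevision",
    version = as.character(utils::packageVersion("dosevision")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)
  ), extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(prov)
}

#' Generate a corpus and write it to disk
#'
#' Renders a training, test (pseudo-real) or OOD corpus and writes PNGs plus
#' a CSV manifest. Reruns with the same seed are byte-identical; a non-empty
#' output directory is refused unless `force = TRUE`.
#'
#' @param out_dir output directory.
#' @param form dosage form (ignored for `role = "ood"` with explicit `kind`).
#' @param role `"train"`, `"test"` or `"ood"`.
#' @param n total images (for `"train"`, split 50:50 good:bad).
#' @param seed root seed.
#' @param kind OOD distractor kind (required for `role = "ood"`).
#' @param canvas_px canvas side; defaults to 512 (train) or 1024 (test/OOD).
#' @param force overwrite non-empty `out_dir`.
#' @return the manifest data.frame, invisibly.
#' @export
qc_generate <- function(out_dir, form = "capsule",
                        role = c("train", "test", "ood"),
                        n = 200L, seed = 1L, kind = NULL, canvas_px = NULL,
                        force = FALSE) {
  role <- match.arg(role)
  ds <- switch(role,
    train = generate_training_set(form, n_good = n %/% 2L, n_bad = n - n %/% 2L,
                                  seed = seed,
                                  canvas_px = canvas_px %||% 512L),
    test = generate_pseudo_real_set(form, n = n, seed = seed,
                                    canvas_px = canvas_px %||% 1024L),
    ood = {
      if (is.null(kind)) stop("role = 'ood' requires `kind`", call. = FALSE)
      generate_ood_set(ood_spec(kind, n = n, canvas_px = canvas_px %||% 1024L,
                                seed = seed))
    })
  write_dataset(ds, out_dir, force = force)
}

#' Exploratory data analysis of an image corpus
#'
#' Class counts and ratio, defect-subtype counts, PNG-encoded byte-size
#' summary (mean and sd), and per-channel intensity histograms. Accepts a
#' directory written by [qc_generate()]/[write_dataset()] or an in-memory
#' [qc_dataset].
#'
#' @param x dataset directory or [qc_dataset].
#' @param hist_breaks number of intensity bins for the channel histograms.
#' @return a list of class `qc_eda`.
#' @export
qc_eda <- function(x, hist_breaks = 32L) {
  if (is.character(x)) {
    sizes <- {
      mf <- file.path(x, "manifest.csv")
      if (!file.exists(mf)) stop("no manifest.csv in ", x, call. = FALSE)
      manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
      file.size(file.path(x, manifest$filename))
    }
    ds <- read_dataset(x)
  } else {
    ds <- x
    sizes <- vapply(ds$items, function(i) {
      length(png::writePNG(i$pixels / 255))
    }, numeric(1))
  }
  lb <- dataset_labels(ds)
  breaks <- seq(0, 256, length.out = hist_breaks + 1L)
  hists <- list()
  for (ch in c("R", "G", "B")) {
    ci <- match(ch, c("R", "G", "B"))
    v <- unlist(lapply(ds$items, function(i) {
      px <- i$pixels
      if (is.matrix(px)) as.vector(px) else as.vector(px[, , ci])
    }))
    hists[[ch]] <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  }
  structure(list(
    n = length(ds),
    class_counts = c(good = sum(lb == "good"), bad = sum(lb == "bad")),
    class_ratio = sum(lb == "good") / length(ds),
    defect_counts = defect_counts(ds),
    byte_size = c(mean = mean(sizes), sd = stats::sd(sizes)),
    channel_histograms = hists,
    hist_breaks = breaks
  ), class = "qc_eda")
}

#' @export
print.qc_eda <- function(x, ...) {
  cat(sprintf("<qc_eda n=%d good=%d bad=%d ratio=%.2f bytes=%.0f+-%.0f>\n",
              x$n, x$class_counts["good"], x$class_counts["bad"],
              x$class_ratio, x$byte_size["mean"], x$byte_size["sd"]))
  cat("  defects:", paste(names(x$defect_counts), x$defect_counts,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.qc_eda <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$class_counts, main = "Class balance", col = c("forestgreen", "firebrick"))
  mids <- (utils::head(x$hist_breaks, -1) + utils::tail(x$hist_breaks, -1)) / 2
  graphics::matplot(mids, do.call(cbind, x$channel_histograms), type = "l",
                    lty = 1, col = c("red", "green3", "blue"),
                    xlab = "intensity", ylab = "count", main = "Channel histograms")
  invisible(x)
}

#' Run the full classification experiment sweep
#'
#' For every form, generates the virtual training corpus and the
#' domain-shifted pseudo-real test corpus, then sweeps image size,
#' color space and technique, training a tuned model per cell and writing a
#' metrics grid. Cells whose fits exceed resource limits are logged, not
#' fatal. The results tree is append-only: each invocation writes into a
#' fresh `run-NNN` directory.
#'
#' @param config an [experiment_config].
#' @param write write CSV/JSON artifacts to `config$out_dir`? Set `FALSE` to
#'   just return results.
#' @return list with `grid` (data.frame over all cells), `best` (best cell
#'   per form), `exceeded` (log of exceeded-limits cells), `run_dir`.
#' @export
qc_run <- function(config = experiment_config(), write = TRUE) {
  run_dir <- if (write) .next_run_dir(config$out_dir) else NULL
  rows <- list(); exceeded <- list()
  for (form in config$forms) {
    message(sprintf("[dosevision] form=%s: generating corpora", form))
    train <- generate_training_set(form, config$n_train_good, config$n_train_bad,
                                   seed = config$seed,
                                   canvas_px = config$train_canvas_px)
    test <- generate_pseudo_real_set(form, config$n_test,
                                     seed = config$seed + 1L,
                                     canvas_px = config$test_canvas_px)
    for (size in config$sizes) {
      for (space in config$color_spaces) {
        cfg <- preprocess_config(size, space, "unit_0_1")
        fm_train <- flatten_images(preprocess_dataset(train, cfg), cfg)
        fm_test <- flatten_images(preprocess_dataset(test, cfg), cfg)
        for (tech in config$techniques) {
          cell <- sprintf("%s/%dpx/%s/%s", form, size, space, tech)
          res <- tryCatch({
            model <- qc_train(fm_train, technique = tech, tuned = TRUE,
                              seed = config$seed, limits = config$limits)
            if (model$status != "ok") {
              exceeded[[cell]] <- model$reason
              message(sprintf("[dosevision] %s: %s", cell, model$reason))
              NULL
            } else {
              rep <- evaluate_model(model, fm_test)
              metrics_row(rep, form = form, size = size, color_space = space,
                          technique = tech)
            }
          }, error = function(e) {
            exceeded[[cell]] <<- conditionMessage(e)
            message(sprintf("[dosevision] %s failed: %s", cell, conditionMessage(e)))
            NULL
          })
          if (!is.null(res)) rows[[cell]] <- res
          message(sprintf("[dosevision] %s done", cell))
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  best <- NULL
  if (!is.null(grid) && nrow(grid) > 0) {
    best <- do.call(rbind, lapply(split(grid, grid$form), function(g)
      g[which.max(g$accuracy), , drop = FALSE]))
  }
  if (write) {
    utils::write.csv(grid, file.path(run_dir, "metrics_grid.csv"), row.names = FALSE)
    if (!is.null(best))
      utils::write.csv(best, file.path(run_dir, "best_cells.csv"), row.names = FALSE)
    jsonlite::write_json(exceeded, file.path(run_dir, "exceeded_limits.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .write_provenance(run_dir, config)
  }
  list(grid = grid, best = best, exceeded = exceeded, run_dir = run_dir)
}

#' Run the robustness stress program
#'
#' Scalability on the 16x-augmented test set, confidence histograms, and the
#' OOD battery with tuned and untuned variants of each technique, per form.
#'
#' @param config an [experiment_config]; only its forms, counts, canvases and
#'   seed are used.
#' @param stress a [stress_config].
#' @param write write CSVs under `config$out_dir`?
#' @return list with `scalability` (grid data.frame), `ood` (data.frame),
#'   `confidence` (per-cell histograms), `run_dir`.
#' @export
qc_stress <- function(config = experiment_config(), stress = stress_config(),
                      write = TRUE) {
  run_dir <- if (write) .next_run_dir(config$out_dir) else NULL
  scal <- list(); oodr <- list(); conf <- list()
  for (form in config$forms) {
    message(sprintf("[dosevision] stress form=%s", form))
    train <- generate_training_set(form, config$n_train_good, config$n_train_bad,
                                   seed = config$seed,
                                   canvas_px = config$train_canvas_px)
    test <- generate_pseudo_real_set(form, config$n_test,
                                     seed = config$seed + 1L,
                                     canvas_px = config$test_canvas_px)
    sc <- run_scalability(train, test, stress)
    sc$grid$form <- form
    scal[[form]] <- sc$grid
    for (key in names(sc$reports)) {
      rep <- sc$reports[[key]]
      conf[[paste(form, key, sep = "_")]] <- list(
        histogram = confidence_report_from_profile(rep$confidence_profile),
        brier = rep$brier)
    }
    # OOD: tuned models reused from the scalability fits; untuned trained here
    for (size in stress$sizes) {
      cfg <- preprocess_config(size, "gray", "unit_0_1")
      fm_train <- flatten_images(preprocess_dataset(train, cfg), cfg)
      models <- list()
      for (tech in stress$techniques) {
        models[[paste0(tech, "_tuned")]] <-
          sc$models[[tech]][[as.character(size)]]
        models[[paste0(tech, "_untuned")]] <-
          qc_train(fm_train, technique = tech, tuned = FALSE, seed = config$seed)
      }
      od <- run_ood(models, form, size, n_per_kind = stress$n_ood_per_kind,
                    seed = stress$seed)
      od$form <- form
      oodr[[paste(form, size)]] <- od
    }
  }
  out <- list(scalability = do.call(rbind, scal),
              ood = do.call(rbind, oodr),
              confidence = conf, run_dir = run_dir)
  if (write) {
    utils::write.csv(out$scalability, file.path(run_dir, "scalability_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ood, file.path(run_dir, "ood_report.csv"),
                     row.names = FALSE)
    ch <- do.call(rbind, lapply(names(conf), function(k)
      data.frame(cell = k, bin = names(conf[[k]]$histogram),
                 count = as.integer(conf[[k]]$histogram),
                 brier = conf[[k]]$brier, stringsAsFactors = FALSE)))
    utils::write.csv(ch, file.path(run_dir, "confidence_histograms.csv"),
                     row.names = FALSE)
    .write_provenance(run_dir, config, list(stress = unclass(stress)))
  }
  out
}

# histogram of an already-computed most-confident profile (0.05-wide bins)
confidence_report_from_profile <- function(mc) {
  breaks <- seq(0.5, 1, by = 0.05)
  bin <- findInterval(mc, breaks, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  names(counts) <- sprintf("[%.2f,%.2f%s", utils::head(breaks, -1),
                           utils::tail(breaks, -1),
                           c(rep(")", length(breaks) - 2L), "]"))
  counts
}

#' Save and load fitted models
#'
#' Models persist as a versioned binary artifact (RDS) with a JSON sidecar
#' recording technique, tuning state, best parameters, feature dimension and
#' class order, so saved models are auditable without loading them.
#'
#' @param model a `qc_model`.
#' @param path `.rds` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `qc_save_model()` returns `path` invisibly; `qc_load_model()` the
#'   model.
#' @export
qc_save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(technique = model$technique, tuned = model$tuned,
               status = model$status,
               best_params = model$best_params, d = model$d,
               class_order = model$classes,
               package_version = as.character(utils::packageVersion("dosevision")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname qc_save_model
#' @export
qc_load_model <- function(path) readRDS(path)

#' Classify user-supplied images with a fitted model
#'
#' Reads PNG files, applies the standard preprocessing path (grayscale or
#' RGB to match the model's training dimension, square resize) and predicts.
#'
#' @param model a `qc_model`.
#' @param files character vector of PNG/JPEG paths (PNG supported natively).
#' @param size image size the model was trained at; inferred from the
#'   model's feature dimension when possible (`d = S^2` gray or `3 S^2` rgb).
#' @return data.frame with file, predicted label and good-class probability.
#' @export
qc_predict <- function(model, files, size = NULL) {
  d <- model$d
  if (is.null(size)) {
    s_gray <- sqrt(d); s_rgb <- sqrt(d / 3)
    if (s_gray == floor(s_gray)) {
      size <- as.integer(s_gray); space <- "gray"
    } else if (s_rgb == floor(s_rgb)) {
      size <- as.integer(s_rgb); space <- "rgb"
    } else stop("cannot infer image size from model dimension ", d, call. = FALSE)
  } else {
    space <- if (d == size^2) "gray" else "rgb"
  }
  cfg <- preprocess_config(size, space, "unit_0_1")
  items <- lapply(files, read_image_png)
  fm <- flatten_images(preprocess_dataset(qc_dataset(items), cfg), cfg)
  probs <- predict(model, fm, type = "prob")
  data.frame(file = files,
             label = ifelse(probs[, "good"] > 0.5, "good", "bad"),
             p_good = probs[, "good"],
             stringsAsFactors = FALSE)
}
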