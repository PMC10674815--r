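# Small fixtures shared across test files. Everything is generated in code;
# canvases are kept small so the default run stays fast.

tiny_geom <- function(form = "tablet", canvas = 96) {
  form_geometry(form, canvas_px = canvas)
}

tiny_render <- function(form = "tablet", quality = "good", defect = "none",
                        canvas = 96, seed = 1, ...) {
  render_form(render_spec(tiny_geom(form, canvas), quality = quality,
                          defect = defect, seed = seed, ...))
}

# linearly separable two-class toy matrix
toy_separable <- function(n = 20, d = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- factor(ifelse(x[, 1] > 0, "good", "bad"), levels = c("bad", "good"))
  x[, 1] <- x[, 1] + sign(x[, 1])  # widen the margin so trees shatter it
  colnames(x) <- paste0("px", seq_len(d))
  list(x = x, y = y)
}

# XOR pattern replicated with jitter: depth-1 stumps fail, depth >= 2 trees
# separate it
toy_xor <- function(reps = 10, seed = 3) {
  set.seed(seed)
  base <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c("good", "good", "bad", "bad")
  x <- base[rep(1:4, each = reps), ] + matrix(stats::rnorm(8 * reps, 0, 0.05),
                                              4 * reps, 2)
  colnames(x) <- c("px1", "px2")
  list(x = x, y = factor(rep(lab, each = reps), levels = c("bad", "good")))
}

# hand-built degenerate models (constant predictors) for harness tests:
# a 1-NN model whose training labels are all `label`
constant_model <- function(label, d) {
  structure(list(
    technique = "kNN", tuned = TRUE, best_params = list(k = 1),
    cv_results = NULL,
    fit = list(x = matrix(0.5, 2, d), y = factor(c(label, label),
                                                 levels = c("bad", "good")),
               k = 1),
    status = "ok", reason = NULL, classes = c("bad", "good"), d = d,
    feature_names = paste0("px", seq_len(d)), seed = 1L
  ), class = "qc_model")
}

# four-connected component sizes by flood fill (independent of any image
# package; used as the oracle for silhouette/distractor connectivity).
# `min_size` drops speckle components (e.g. clipped noise tails).
count_components <- function(mask, min_size = 1L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  sizes <- integer(0)
  nr <- nrow(mask)
  for (start in seq_along(mask)) {
    if (!mask[start] || lab[start] != 0L) next
    cur <- length(sizes) + 1L
    queue <- start
    lab[start] <- cur
    sz <- 0L
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (cl > 1) p - nr, if (cl < ncol(mask)) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sum(sizes >= min_size)
}
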