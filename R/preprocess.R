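#' Preprocessing configuration
#'
#' @param target_size_px square side after resizing (>= 8). The study sweep
#'   uses 25, 50, 125, 256 and 512, but any size >= 8 is accepted.
#' @param color_space `"gray"` (luma conversion before flattening) or `"rgb"`.
#' @param intensity_scale `"unit_0_1"` (divide by 255; appropriate for
#'   scale-sensitive learners) or `"raw_0_255"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size_px = 125L,
                              color_space = c("gray", "rgb"),
                              intensity_scale = c("unit_0_1", "raw_0_255")) {
  color_space <- match.arg(color_space)
  intensity_scale <- match.arg(intensity_scale)
  if (target_size_px < 8L) stop("target_size_px must be >= 8", call. = FALSE)
  structure(list(target_size_px = as.integer(target_size_px),
                 color_space = color_space,
                 intensity_scale = intensity_scale),
            class = "preprocess_config")
}

#' Convert an image to grayscale
#'
#' Standard-definition luma weights (0.299 R + 0.587 G + 0.114 B) with
#' round-half-up to the nearest integer. Idempotent: a grayscale input is
#' returned unchanged.
#'
#' @param image a [qc_image].
#' @return a grayscale [qc_image] with label, defect and source preserved.
#' @export
to_grayscale <- function(image) {
  if (is_gray(image)) return(image)
  px <- image$pixels
  g <- floor(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3] + 0.5)
  dim(g) <- dim(px)[1:2]
  storage.mode(g) <- "integer"
  out <- image
  out$pixels <- g
  attr(out, "masks") <- NULL   # render masks describe the original raster
  out
}

# Row weight matrix mapping `src` samples to `dst` samples. Area-weighted
# averaging for shrink factors above 2, bilinear (half-pixel centers)
# otherwise. Rows sum to 1, so constant images are preserved exactly.
.resize_weights <- function(src, dst) {
  if (dst == src) return(diag(src))
  scale <- src / dst
  W <- matrix(0, dst, src)
  if (scale > 2) {
    for (i in seq_len(dst)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1L
      j1 <- min(ceiling(hi), src)
      for (j in j0:j1) {
        cover <- min(hi, j) - max(lo, j - 1)
        if (cover > 0) W[i, j] <- cover
      }
      W[i, ] <- W[i, ] / sum(W[i, ])
    }
  } else {
    for (i in seq_len(dst)) {
      sc <- (i - 0.5) * scale - 0.5
      j <- floor(sc)
      fr <- sc - j
      j0 <- min(max(j + 1L, 1L), src)
      j1 <- min(max(j + 2L, 1L), src)
      W[i, j0] <- W[i, j0] + (1 - fr)
      W[i, j1] <- W[i, j1] + fr
    }
  }
  W
}

#' Resize an image to a square
#'
#' Resamples to exactly `size x size` pixels. The aspect ratio is
#' intentionally not preserved: rectangular films are distorted to squares,
#' matching the uniform-square convention the downstream feature matrix
#' requires. Downsampling by more than a factor of 2 uses area-weighted
#' averaging; other scalings are bilinear.
#'
#' @param image a [qc_image].
#' @param size target side in pixels (>= 1; sizes below 8 are allowed here
#'   but rejected by [preprocess_config()]).
#' @return the resized [qc_image].
#' @export
resize_image <- function(image, size) {
  if (length(size) != 1L || is.na(size) || size < 1)
    stop("`size` must be a positive integer", call. = FALSE)
  size <- as.integer(size)
  px <- image$pixels
  d <- dim(px)
  Wr <- .resize_weights(d[1], size)
  Wc <- .resize_weights(d[2], size)
  resample <- function(m) {
    out <- Wr %*% m %*% t(Wc)
    out[out < 0] <- 0
    out[out > 255] <- 255
    out <- floor(out + 0.5)
    storage.mode(out) <- "integer"
    out
  }
  out <- image
  attr(out, "masks") <- NULL
  if (is.matrix(px)) {
    out$pixels <- resample(px)
  } else {
    res <- array(0L, dim = c(size, size, 3))
    for (ch in 1:3) res[, , ch] <- resample(px[, , ch])
    out$pixels <- res
  }
  out
}

#' Center crop
#'
#' Keeps the centered `floor(f * H) x floor(f * W)` window. Smaller fractions
#' make the dosage form occupy a larger share of the (later resized) frame,
#' emulating a shorter imaging distance.
#'
#' @param image a [qc_image].
#' @param fraction crop fraction in `(0, 1]`; 1 is the identity.
#' @return the cropped [qc_image].
#' @export
crop_center <- function(image, fraction) {
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  px <- image$pixels
  d <- dim(px)
  h <- max(1L, floor(fraction * d[1]))
  w <- max(1L, floor(fraction * d[2]))
  r0 <- floor((d[1] - h) / 2) + 1L
  c0 <- floor((d[2] - w) / 2) + 1L
  out <- image
  attr(out, "masks") <- NULL
  if (is.matrix(px)) out$pixels <- px[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  else out$pixels <- px[r0:(r0 + h - 1L), c0:(c0 + w - 1L), , drop = FALSE]
  out
}

#' Reorient an image
#'
#' Exact pixel permutations: horizontal flip, vertical flip, or 180-degree
#' rotation (`rot180(x) == hflip(vflip(x))`). Labels are preserved.
#'
#' @param image a [qc_image].
#' @param which `"identity"`, `"hflip"`, `"vflip"` or `"rot180"`.
#' @return the reoriented [qc_image].
#' @export
orient <- function(image, which = c("identity", "hflip", "vflip", "rot180")) {
  which <- match.arg(which)
  if (which == "identity") return(image)
  px <- image$pixels
  d <- dim(px)
  ri <- if (which %in% c("vflip", "rot180")) rev(seq_len(d[1])) else seq_len(d[1])
  ci <- if (which %in% c("hflip", "rot180")) rev(seq_len(d[2])) else seq_len(d[2])
  out <- image
  attr(out, "masks") <- NULL
  if (is.matrix(px)) out$pixels <- px[ri, ci, drop = FALSE]
  else out$pixels <- px[ri, ci, , drop = FALSE]
  out
}

#' Flatten images into a feature matrix
#'
#' Row-major flattening: grayscale images yield `S^2` features per image, RGB
#' images `3 S^2` (channels interleaved per pixel: R, G, B of pixel (1,1),
#' then pixel (1,2), ...). All images must share identical dimensions and
#' color space.
#'
#' @param dataset a [qc_dataset] (or plain list of [qc_image]).
#' @param config a [preprocess_config]; only `intensity_scale` is consulted
#'   (images are assumed already resized/grayscaled as desired).
#' @return a list of class `feature_matrix` with elements `values`
#'   (`n x d` numeric matrix), `labels` (factor, levels `bad`, `good`),
#'   `defects`, `provenance` (per-row digests) and `config`.
#' @export
flatten_images <- function(dataset, config = preprocess_config()) {
  items <- if (inherits(dataset, "qc_dataset")) dataset$items else dataset
  n <- length(items)
  if (n < 1L) stop("empty dataset", call. = FALSE)
  dims <- lapply(items, function(i) dim(i$pixels))
  ref <- dims[[1]]
  bad <- which(!vapply(dims, function(d) identical(d, ref), logical(1)))
  if (length(bad) > 0)
    stop("images have mixed shapes; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  d <- prod(ref)
  vals <- matrix(0, n, d)
  for (i in seq_len(n)) {
    px <- items[[i]]$pixels
    vals[i, ] <- if (is.matrix(px)) as.vector(t(px))
                 else as.vector(aperm(px, c(3, 2, 1)))
  }
  if (config$intensity_scale == "unit_0_1") vals <- vals / 255
  colnames(vals) <- paste0("px", seq_len(d))
  structure(list(
    values = vals,
    labels = factor(vapply(items, function(i) i$label, character(1)),
                    levels = c("bad", "good")),
    defects = vapply(items, function(i) i$defect, character(1)),
    provenance = vapply(items, function(i) i$digest, character(1)),
    shape = ref,
    config = config
  ), class = "feature_matrix")
}

#' @rdname flatten_images
#' @param row a numeric feature vector produced by [flatten_images()].
#' @param shape the original image dimensions (`c(H, W)` or `c(H, W, 3)`).
#' @param intensity_scale scale the row was stored in.
#' @return `unflatten_image()` returns the pixel raster (matrix or array).
#' @export
unflatten_image <- function(row, shape, intensity_scale = "unit_0_1") {
  v <- if (intensity_scale == "unit_0_1") row * 255 else row
  if (length(shape) == 2L) {
    t(matrix(v, shape[2], shape[1]))
  } else {
    aperm(array(v, dim = c(3, shape[2], shape[1])), c(3, 2, 1))
  }
}

#' Standardize a dataset (grayscale + resize)
#'
#' Applies the preprocessing path used throughout the study: optional luma
#' grayscale conversion followed by square resizing.
#'
#' @param dataset a [qc_dataset].
#' @param config a [preprocess_config].
#' @return the standardized [qc_dataset].
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  items <- lapply(dataset$items, function(img) {
    if (config$color_space == "gray") img <- to_grayscale(img)
    resize_image(img, config$target_size_px)
  })
  out <- dataset
  out$items <- items
  out
}

#' Sixteen-fold test-set augmentation
#'
#' Expands a grayscale test set by the cross of 4 center-crop fractions and 4
#' orientations (identity, hflip, vflip, rot180), so the output holds exactly
#' `16 x` the input images (the identity orientation at fraction closest to 1
#' carries the least-altered view of each original). Labels and defects are
#' preserved; each output records its provenance (source index, fraction,
#' orientation). Outputs retain their cropped sizes; resize afterwards (e.g.
#' via [preprocess_dataset()]) to restore uniform dimensions.
#'
#' @param dataset a grayscale [qc_dataset].
#' @param fractions 4 distinct crop fractions in `(0, 1]`.
#' @return a [qc_dataset] of `16 * length(dataset)` augmented images.
#' @export
augment_test_set <- function(dataset, fractions = c(0.9, 0.8, 0.7, 0.6)) {
  if (length(fractions) != 4L || anyDuplicated(fractions) > 0)
    stop("`fractions` must be 4 distinct crop fractions", call. = FALSE)
  if (any(vapply(dataset$items, function(i) !is_gray(i), logical(1))))
    stop("augmentation expects grayscale images; apply to_grayscale() first",
         call. = FALSE)
  items <- vector("list", 16L * length(dataset))
  k <- 0L
  for (i in seq_along(dataset$items)) {
    out16 <- .augment_one(dataset$items[[i]], i, fractions)
    items[(k + 1L):(k + 16L)] <- out16
    k <- k + 16L
  }
  qc_dataset(items, form = dataset$metadata$form, seed = dataset$metadata$seed,
             role = "augmented", fractions = fractions)
}

# The 16 augmented views (4 crops x 4 orientations) of one grayscale image,
# in the canonical order used by augment_test_set() and the streaming
# scalability harness.
.augment_one <- function(src, src_index, fractions) {
  orients <- c("identity", "hflip", "vflip", "rot180")
  out <- vector("list", 16L)
  k <- 0L
  for (f in fractions) {
    cropped <- crop_center(src, f)
    for (o in orients) {
      k <- k + 1L
      img <- orient(cropped, o)
      img$source <- "augmented"
      img$digest <- sprintf("%s|src=%d|f=%g|orient=%s", src$digest, src_index, f, o)
      out[[k]] <- img
    }
  }
  out
}
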