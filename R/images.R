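#' Labeled image container
#'
#' A `qc_image` bundles a pixel raster with its quality label, defect subtype
#' and provenance. Rasters are either an `H x W x 3` RGB array or an `H x W`
#' single-channel (grayscale) matrix; intensities are integers in `[0, 255]`
#' with origin at the top-left and row-major pixel order.
#'
#' @param pixels numeric matrix (grayscale) or `H x W x 3` array (RGB) with
#'   values in `[0, 255]`.
#' @param label quality class, `"good"` or `"bad"`.
#' @param defect defect subtype: `"none"`, `"cracked"`, `"over_cured"` or
#'   `"under_cured"`. For rendered prints `"none"` pairs with `label "good"`
#'   (enforced by [render_spec()]); out-of-distribution images are labeled
#'   `"bad"` with defect `"none"` since they depict no print at all.
#' @param source provenance: one of `"virtual"`, `"pseudo_real"`, `"ood"`,
#'   `"augmented"`, `"user"`.
#' @param digest optional provenance string describing how the raster was made.
#' @return an object of class `qc_image`.
#' @export
qc_image <- function(pixels, label = c("good", "bad"),
                     defect = c("none", "cracked", "over_cured", "under_cured"),
                     source = c("user", "virtual", "pseudo_real", "ood", "augmented"),
                     digest = NULL) {
  label <- match.arg(label)
  defect <- match.arg(defect)
  source <- match.arg(source)
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L &&
                              dim(pixels)[3] == 3L)))
    stop("`pixels` must be an H x W matrix or an H x W x 3 array", call. = FALSE)
  if (any(dim(pixels)[1:2] < 1L)) stop("image must have H >= 1, W >= 1", call. = FALSE)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  structure(
    list(pixels = pixels, label = label, defect = defect, source = source,
         digest = digest %||% ""),
    class = "qc_image"
  )
}

#' @export
print.qc_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) "RGB" else "gray"
  cat(sprintf("<qc_image %dx%d %s label=%s defect=%s source=%s>\n",
              d[1], d[2], ch, x$label, x$defect, x$source))
  invisible(x)
}

#' @export
dim.qc_image <- function(x) dim(x$pixels)

is_gray <- function(image) is.matrix(image$pixels)

#' Image dataset container
#'
#' An ordered collection of [qc_image] items plus generation metadata.
#'
#' @param items list of `qc_image` objects.
#' @param form dosage form the dataset depicts (or `NA` for mixed/OOD sets).
#' @param seed root seed used by the generator, if any.
#' @param ... further metadata fields stored verbatim.
#' @return an object of class `qc_dataset`.
#' @export
qc_dataset <- function(items, form = NA_character_, seed = NA_integer_, ...) {
  stopifnot(is.list(items))
  for (it in items)
    if (!inherits(it, "qc_image")) stop("all items must be qc_image objects", call. = FALSE)
  structure(
    list(items = items,
         metadata = list(form = form, seed = seed,
                         generator = paste0("dosevision-", utils::packageVersion("dosevision")),
                         ...)),
    class = "qc_dataset"
  )
}

#' @export
length.qc_dataset <- function(x) length(x$items)

#' @export
print.qc_dataset <- function(x, ...) {
  lb <- dataset_labels(x)
  cat(sprintf("<qc_dataset n=%d form=%s good=%d bad=%d>\n",
              length(x), x$metadata$form, sum(lb == "good"), sum(lb == "bad")))
  invisible(x)
}

#' Class and defect composition of a dataset
#'
#' @param dataset a [qc_dataset].
#' @return `dataset_labels()` returns the character vector of labels;
#'   `defect_counts()` a named integer vector of defect subtype counts among
#'   the 'bad' items (cracked, over_cured, under_cured).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$items, function(i) i$label, character(1))
}

#' @rdname dataset_labels
#' @export
defect_counts <- function(dataset) {
  dft <- vapply(dataset$items, function(i) i$defect, character(1))
  tab <- table(factor(dft[dft != "none"],
                      levels = c("cracked", "over_cured", "under_cured")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read and write 8-bit PNG images
#'
#' Images are stored as 8-bit PNG; reading and writing round-trips pixel
#' intensities exactly.
#'
#' @param image a [qc_image].
#' @param path file path.
#' @param label,defect,source metadata attached to the image on read.
#' @return `write_image_png()` returns `path` invisibly; `read_image_png()`
#'   a [qc_image].
#' @export
write_image_png <- function(image, path) {
  px <- image$pixels
  if (is.matrix(px)) {
    png::writePNG(px / 255, target = path)
  } else {
    png::writePNG(px / 255, target = path)
  }
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path, label = "good", defect = "none", source = "user") {
  raw <- png::readPNG(path)
  px <- round(raw * 255)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1L]          # gray + alpha
    else if (dim(px)[3] == 4L) px <- px[, , 1:3]    # drop alpha
    else if (dim(px)[3] == 1L) px <- px[, , 1L]
  }
  qc_image(px, label = label, defect = defect, source = source,
           digest = paste0("file:", basename(path)))
}

#' Write a dataset to a directory of PNG files with a CSV manifest
#'
#' Files are named `{form}_{label}_{defect}_{index}.png`; the manifest
#' (`manifest.csv`) records filename, form, label, defect and the root seed.
#'
#' @param dataset a [qc_dataset].
#' @param dir output directory (created if missing).
#' @param force overwrite a non-empty directory.
#' @return the manifest as a data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  form <- dataset$metadata$form
  n <- length(dataset)
  fn <- character(n)
  for (i in seq_len(n)) {
    it <- dataset$items[[i]]
    fn[i] <- sprintf("%s_%s_%s_%04d.png",
                     if (is.na(form)) it$source else form, it$label, it$defect, i)
    write_image_png(it, file.path(dir, fn[i]))
  }
  manifest <- data.frame(
    filename = fn,
    form = rep(if (is.na(form)) "" else form, n),
    label = dataset_labels(dataset),
    defect = vapply(dataset$items, function(i) i$defect, character(1)),
    seed = rep(dataset$metadata$seed, n),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  items <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    items[[i]] <- read_image_png(file.path(dir, manifest$filename[i]),
                                 label = manifest$label[i],
                                 defect = manifest$defect[i])
  }
  qc_dataset(items, form = manifest$form[1] %||% NA_character_,
             seed = manifest$seed[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
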