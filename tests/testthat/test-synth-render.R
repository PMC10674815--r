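# Procedural rasterizer: geometry fidelity, determinism, defect conventions,
# corpus composition.

test_that("tablet silhouette area matches the analytic disc", {
  g <- form_geometry("tablet", px_per_mm = 20, canvas_px = 512)
  img <- render_form(render_spec(g, "good", "none", seed = 5))
  gray <- to_grayscale(img)$pixels
  # segment foreground by brightness: print bodies are far brighter than the
  # dark enclosure
  fg <- sum(gray > 80)
  expect_lt(abs(fg - pi * 100^2) / (pi * 100^2), 0.02)
})

test_that("film bounding box has the 3:1 footprint aspect ratio", {
  img <- render_form(render_spec(form_geometry("film", canvas_px = 256),
                                 "good", "none", seed = 2))
  gray <- to_grayscale(img)$pixels
  fg <- gray > 80
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  aspect <- diff(cols) / diff(rows)
  expect_lt(abs(aspect - 3) / 3, 0.05)
})

test_that("geometry fidelity holds across forms and raster scales", {
  for (form in c("tablet", "capsule", "film")) {
    for (ppm in c(5, 12)) {
      geom <- form_geometry(form, px_per_mm = ppm,
                            canvas_px = max(96, ceiling(2.3 * ppm *
                              max(form_geometry(form)$length_mm, 10))))
      img <- render_form(render_spec(geom, "good", "none", seed = 7,
                                     noise_sd = 0))
      fg <- to_grayscale(img)$pixels > 80
      a <- geom$length_mm / 2 * ppm
      b <- geom$width_mm / 2 * ppm
      want <- switch(form,
                     tablet = pi * a * b,
                     film = 4 * a * b,
                     capsule = pi * b^2 + 2 * (a - b) * 2 * b)
      expect_lt(abs(sum(fg) - want) / want, 0.05,
                label = sprintf("%s at %g px/mm area error", form, ppm))
    }
  }
})

test_that("rendering is a pure function of the spec", {
  sp <- render_spec(tiny_geom("capsule"), "bad", "cracked", seed = 9)
  i1 <- render_form(sp)
  i2 <- render_form(sp)
  expect_identical(i1$pixels, i2$pixels)
  # different seed moves the sensor noise
  sp2 <- render_spec(tiny_geom("capsule"), "bad", "cracked", seed = 10)
  expect_false(identical(render_form(sp2)$pixels, i1$pixels))
})

test_that("inconsistent quality/defect pairs and oversized prints are rejected", {
  expect_error(render_spec(tiny_geom(), "good", "cracked"), "inconsistent")
  expect_error(render_spec(tiny_geom(), "bad", "none"), "inconsistent")
  expect_error(form_geometry("tablet", px_per_mm = 100, canvas_px = 128),
               "margin")
})

test_that("cracks are connected dark polylines spanning the body", {
  img <- tiny_render("tablet", "bad", "cracked", canvas = 256, seed = 21)
  masks <- attr(img, "masks")
  crack <- masks$crack
  sil <- masks$silhouette
  expect_gt(sum(crack), 0)
  expect_true(all(sil[crack]))  # crack lies inside the silhouette
  # trace one crack component and check its endpoints sit within 3 px of the
  # silhouette boundary
  lab <- which(crack, arr.ind = TRUE)
  ctr <- colMeans(lab)
  d2c <- (lab[, 1] - ctr[1])^2 + (lab[, 2] - ctr[2])^2
  e1 <- lab[which.max(d2c), ]
  d2e <- (lab[, 1] - e1[1])^2 + (lab[, 2] - e1[2])^2
  e2 <- lab[which.max(d2e), ]
  boundary <- which(sil & !(rbind(sil[-1, ], FALSE) & rbind(FALSE, sil[-nrow(sil), ]) &
                            cbind(sil[, -1], FALSE) & cbind(FALSE, sil[, -ncol(sil)])),
                    arr.ind = TRUE)
  for (e in list(e1, e2)) {
    dmin <- sqrt(min((boundary[, 1] - e[1])^2 + (boundary[, 2] - e[2])^2))
    expect_lte(dmin, 3)
  }
  # crack pixels are darker than the surrounding body
  gray <- to_grayscale(img)$pixels
  expect_lt(mean(gray[crack]), 0.6 * mean(gray[sil & !crack]))
})

test_that("over-cured prints dilate and under-cured prints erode the silhouette", {
  good <- attr(tiny_render("tablet", canvas = 192, seed = 3), "masks")$silhouette
  over <- attr(tiny_render("tablet", "bad", "over_cured", canvas = 192, seed = 3),
               "masks")$silhouette
  under <- attr(tiny_render("tablet", "bad", "under_cured", canvas = 192, seed = 3),
                "masks")$silhouette
  expect_gt(sum(over), 1.08 * sum(good))
  expect_lt(sum(under), 0.85 * sum(good))
})

test_that("training corpus composition follows the requested counts", {
  ds <- generate_training_set("tablet", 2, 3, seed = 7, canvas_px = 96)
  expect_equal(length(ds), 5L)
  expect_equal(unname(defect_counts(ds)), c(1L, 1L, 1L))
  expect_error(generate_training_set("tablet", 2, 2, canvas_px = 96), "n_bad")
  # remainder of the even split goes to cracked
  ds2 <- generate_training_set("film", 1, 7, seed = 1, canvas_px = 96)
  expect_equal(defect_counts(ds2)[["cracked"]], 3L)
})

test_that("corpus generation is deterministic and seed-sensitive", {
  a <- generate_training_set("capsule", 3, 3, seed = 4, canvas_px = 96)
  b <- generate_training_set("capsule", 3, 3, seed = 4, canvas_px = 96)
  c <- generate_training_set("capsule", 3, 3, seed = 5, canvas_px = 96)
  expect_identical(lapply(a$items, `[[`, "pixels"),
                   lapply(b$items, `[[`, "pixels"))
  expect_false(identical(a$items[[1]]$pixels, c$items[[1]]$pixels))
})

test_that("pseudo-real sets are balanced, near-grayscale and larger-canvas", {
  expect_error(generate_pseudo_real_set("tablet", 7, canvas_px = 192), "even")
  ds <- generate_pseudo_real_set("tablet", 6, seed = 0, canvas_px = 192)
  lb <- dataset_labels(ds)
  expect_equal(sum(lb == "good"), 3L)
  expect_equal(unname(defect_counts(ds)), c(1L, 1L, 1L))
  # per-pixel channel spread bounded: low-chroma palette + luminance-locked
  # noise (bound: 15 intensity units + 3 * noise_sd)
  for (it in ds$items) {
    px <- it$pixels
    expect_lte(max(abs(px[, , 1] - px[, , 2])), 15 + 3 * 6)
    expect_lte(max(abs(px[, , 2] - px[, , 3])), 15 + 3 * 6)
  }
  # default canvas is twice the training default
  expect_gte(1024, 2 * 512)
})

test_that("OOD noise images have near-uniform channel histograms", {
  ds <- generate_ood_set(ood_spec("noise", 3, canvas_px = 64, seed = 5))
  expect_equal(length(ds), 3L)
  for (it in ds$items) {
    counts <- tabulate(findInterval(as.vector(it$pixels), seq(0, 256, 16),
                                    rightmost.closed = TRUE), 16)
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("OOD backgrounds are near-constant dark canvases", {
  ds <- generate_ood_set(ood_spec("background", 1, canvas_px = 64, seed = 0))
  px <- ds$items[[1]]$pixels
  expect_lte(stats::sd(px), 4)
  expect_lte(mean(px), 60)
})

test_that("OOD shapes are single connected components labeled bad", {
  ds <- generate_ood_set(ood_spec("oblong", 10, canvas_px = 128, seed = 2))
  expect_true(all(dataset_labels(ds) == "bad"))
  for (it in ds$items) {
    gray <- to_grayscale(it)$pixels
    mask <- gray > 64   # dark enclosure vs bright shape fill
    expect_equal(count_components(mask, min_size = 9L), 1L)
  }
  expect_error(generate_ood_set(ood_spec("hexagon", 1)), "arg")
})

test_that("matched-geometry distractors follow the form", {
  expect_equal(matched_ood_shape("capsule"), "oblong")
  expect_equal(matched_ood_shape("tablet"), "circle")
  expect_equal(matched_ood_shape("film"), "diamond")
  expect_equal(ood_kinds("film"), c("background", "noise", "triangle", "diamond"))
})

test_that("defect renderings are learnable within the virtual domain", {
  # a depth-unlimited decision tree trained on 136 virtual images must reach
  # >= 90% accuracy on 64 held-out ones, otherwise downstream transfer
  # experiments are vacuous
  std <- function(img) resize_image(to_grayscale(img), 256)
  ds <- generate_training_set("tablet", 100, 100, seed = 1, canvas_px = 512,
                              transform = std)
  fm <- flatten_images(ds, preprocess_config(256, "gray", "unit_0_1"))
  set.seed(42)
  idx <- sample(200, 64)
  dt <- qc_train(fm$values[-idx, ], fm$labels[-idx], technique = "DT",
                 tuned = FALSE, seed = 1)
  acc <- mean(predict(dt, fm$values[idx, ], type = "label") == fm$labels[idx])
  expect_gte(acc, 0.90)
})
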