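#' Dosage-form geometry
#'
#' Describes the top-down footprint of a dosage form in millimetres together
#' with the raster scale. Defaults follow common SLA print designs: films
#' 30 x 10 mm, tablets 10 mm diameter, capsules 18 x 8 mm. Heights are not
#' part of the geometry because all renders are top-down views.
#'
#' @param form `"capsule"`, `"tablet"` or `"film"`.
#' @param length_mm,width_mm footprint in mm (for tablets both equal the
#'   diameter). `NULL` selects the form default.
#' @param px_per_mm raster scale. `NULL` selects the largest scale that keeps
#'   a 15% margin on every side of the canvas.
#' @param canvas_px side of the square canvas in pixels.
#' @return an object of class `form_geometry`.
#' @export
form_geometry <- function(form = c("capsule", "tablet", "film"),
                          length_mm = NULL, width_mm = NULL,
                          px_per_mm = NULL, canvas_px = 512L) {
  form <- match.arg(form)
  def <- switch(form,
                film    = c(30, 10),
                tablet  = c(10, 10),
                capsule = c(18, 8))
  length_mm <- length_mm %||% def[1]
  width_mm <- width_mm %||% def[2]
  if (length_mm <= 0 || width_mm <= 0 || canvas_px < 16)
    stop("geometry dimensions must be positive and canvas_px >= 16", call. = FALSE)
  px_per_mm <- px_per_mm %||% (0.70 * canvas_px / max(length_mm, width_mm))
  half_max_px <- max(length_mm, width_mm) / 2 * px_per_mm
  if (half_max_px > 0.45 * canvas_px)
    stop("silhouette does not fit the canvas with a 5% margin; ",
         "reduce px_per_mm or enlarge canvas_px", call. = FALSE)
  structure(list(form = form, length_mm = length_mm, width_mm = width_mm,
                 px_per_mm = px_per_mm, canvas_px = as.integer(canvas_px)),
            class = "form_geometry")
}

#' Parametric description of one synthetic dosage-form image
#'
#' Everything [render_form()] needs to produce one image deterministically:
#' geometry, quality/defect, base color, SLA layer-line texture, background
#' shade, sensor noise and the seed. The quality/defect pair must be
#' consistent: `"good"` with `"none"`, `"bad"` with a defect subtype.
#'
#' @param geometry a [form_geometry].
#' @param quality `"good"` or `"bad"`.
#' @param defect `"none"`, `"cracked"`, `"over_cured"` or `"under_cured"`.
#' @param base_color RGB triple in `[0, 255]` for the print body.
#' @param layer_texture list with `spacing_px` (layer-line period) and
#'   `amplitude` (peak darkening, intensity units).
#' @param background_shade background gray level in `[0, 255]`.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param chroma_locked apply the same noise to all three channels (luminance
#'   noise, as in near-grayscale photographs) instead of independent
#'   per-channel noise.
#' @param rotation_deg,offset_px in-plane pose jitter applied to the print.
#' @param seed integer seed; identical specs render byte-identically.
#' @param defect_seed seed for the defect *geometry* (crack polyline, rim
#'   dilation, erosion chunks). Defaults to `seed`. Corpus generators hold it
#'   fixed across a dataset so that every defective image depicts the same
#'   physical defect design -- mirroring production of defective prints from
#'   one CAD model per defect type -- while colors, pose and noise vary.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(geometry,
                        quality = c("good", "bad"),
                        defect = c("none", "cracked", "over_cured", "under_cured"),
                        base_color = c(200, 160, 60),
                        layer_texture = list(spacing_px = 8, amplitude = 30),
                        background_shade = 30,
                        noise_sd = 5,
                        chroma_locked = FALSE,
                        rotation_deg = 0,
                        offset_px = c(0, 0),
                        seed = 1L,
                        defect_seed = NULL) {
  quality <- match.arg(quality)
  defect <- match.arg(defect)
  if (!inherits(geometry, "form_geometry"))
    stop("`geometry` must be a form_geometry", call. = FALSE)
  if ((quality == "good") != (defect == "none"))
    stop("inconsistent quality/defect pair: 'good' <=> 'none'", call. = FALSE)
  if (length(base_color) != 3L || any(base_color < 0) || any(base_color > 255))
    stop("base_color must be an RGB triple in [0, 255]", call. = FALSE)
  if (layer_texture$spacing_px <= 0 || layer_texture$amplitude < 0 ||
      layer_texture$amplitude > 255)
    stop("invalid layer_texture", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(geometry = geometry, quality = quality, defect = defect,
                 base_color = as.numeric(base_color),
                 layer_texture = layer_texture,
                 background_shade = background_shade,
                 noise_sd = noise_sd, chroma_locked = chroma_locked,
                 rotation_deg = rotation_deg, offset_px = offset_px,
                 seed = as.integer(seed),
                 defect_seed = as.integer(defect_seed %||% seed)),
            class = "render_spec")
}

# Membership test for the (convex) form silhouette, scaled by `scale`.
# X, Y are pixel-center coordinates relative to the print center, X along
# the length axis.
.silhouette_mask <- function(form, length_mm, width_mm, px_per_mm, scale, X, Y) {
  a <- length_mm / 2 * px_per_mm * scale
  b <- width_mm / 2 * px_per_mm * scale
  switch(form,
         tablet = (X / a)^2 + (Y / b)^2 <= 1,
         film = abs(X) <= a & abs(Y) <= b,
         capsule = {
           core <- pmax(abs(X) - (a - b), 0)
           core^2 + Y^2 <= b^2
         })
}

# Distance from the print center to the silhouette edge along direction
# `theta`, found by bisection (all silhouettes are convex and star-shaped).
.edge_radius <- function(spec, theta, scale = 1) {
  g <- spec$geometry
  hi <- max(g$length_mm, g$width_mm) * g$px_per_mm
  lo <- 0
  u <- c(cos(theta), sin(theta))
  for (k in 1:30) {
    mid <- (lo + hi) / 2
    inside <- .silhouette_mask(g$form, g$length_mm, g$width_mm, g$px_per_mm,
                               scale, mid * u[1], mid * u[2])
    if (inside) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Illumination field: radial vignette times a top-left luminance gradient.
# Depends only on the canvas side, so it is memoized per size.
.shade_cache <- new.env(parent = emptyenv())
.shade_field <- function(n) {
  key <- as.character(n)
  if (!is.null(.shade_cache[[key]])) return(.shade_cache[[key]])
  idx <- seq_len(n) - 0.5
  rmax2 <- 2 * (n / 2)^2
  vx <- (idx - n / 2)^2
  shade <- (1 - 0.12 * outer(vx, vx, "+") / rmax2) *
    (1.05 - 0.10 * outer(idx, idx, "+") / (2 * n))
  .shade_cache[[key]] <- shade
  shade
}

# Mask of pixels within `halfwidth` of a polyline given as an m x 2 matrix
# of (x, y) points in the rotated print frame.
.polyline_mask <- function(X, Y, pts, halfwidth) {
  mask <- matrix(FALSE, nrow(X), ncol(X))
  hw2 <- halfwidth^2
  for (s in seq_len(nrow(pts) - 1L)) {
    p <- pts[s, ]; q <- pts[s + 1L, ]
    v <- q - p
    L2 <- sum(v^2)
    if (L2 == 0) next
    tpar <- ((X - p[1]) * v[1] + (Y - p[2]) * v[2]) / L2
    tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
    d2 <- (X - p[1] - tpar * v[1])^2 + (Y - p[2] - tpar * v[2])^2
    mask <- mask | (d2 <= hw2)
  }
  mask
}

#' Render one synthetic dosage-form image
#'
#' Deterministic software rasterizer: the same spec (including seed) always
#' produces a byte-identical raster. The print silhouette is drawn at the
#' millimetre geometry of the spec, overlaid with a sinusoidal SLA layer-line
#' texture, shaded by a radial vignette plus a top-left illumination gradient,
#' and finished with additive Gaussian sensor noise.
#'
#' Defect conventions (the defect subtypes are named after SLA failure modes;
#' their visual signatures are this package's declared conventions):
#' \describe{
#'   \item{cracked}{1-3 dark jagged polylines spanning the body, line width
#'     1-3% of the smaller silhouette dimension.}
#'   \item{over_cured}{silhouette dilated by 5-15% with a darkened,
#'     soft-edged rim of excess polymerized resin.}
#'   \item{under_cured}{silhouette eroded by 10-18% with 1-3 missing boundary
#'     chunks, and the body alpha-blended toward the background (incomplete
#'     cure leaves translucent resin).}
#' }
#'
#' @param spec a [render_spec].
#' @return a [qc_image] carrying the label/defect of the spec. The returned
#'   image has an attribute `masks`: a list with the logical silhouette mask
#'   and, for cracked prints, the crack mask.
#' @export
render_form <- function(spec) {
  if (!inherits(spec, "render_spec")) stop("`spec` must be a render_spec", call. = FALSE)
  g <- spec$geometry
  n <- g$canvas_px
  set.seed(spec$seed)

  # pixel-center coordinates relative to (jittered) print center
  idx <- seq_len(n) - 0.5
  cx <- n / 2 + spec$offset_px[1]
  cy <- n / 2 + spec$offset_px[2]
  xv <- idx - cx                               # column coordinate vector
  yv <- idx - cy                               # row coordinate vector
  Xg <- matrix(xv, n, n, byrow = TRUE)
  Yg <- matrix(yv, n, n, byrow = FALSE)
  th <- spec$rotation_deg * pi / 180
  if (th != 0) {
    X <- Xg * cos(th) + Yg * sin(th)
    Y <- -Xg * sin(th) + Yg * cos(th)
  } else {
    X <- Xg; Y <- Yg
  }

  msk <- function(scale) .silhouette_mask(g$form, g$length_mm, g$width_mm,
                                          g$px_per_mm, scale, X, Y)
  min_dim_px <- min(g$length_mm, g$width_mm) * g$px_per_mm

  # Defect geometry: the *design* (crack path, dilation, erosion chunks) is
  # drawn from the defect stream, so a corpus can depict one fixed defect
  # design across many color/pose variants -- defective prints produced from
  # a single CAD model per subtype. A small per-image manufacturing jitter
  # (from the image stream) is layered on top, as no two physical prints of
  # one design are pixel-identical.
  set.seed(spec$defect_seed + match(spec$defect,
                                    c("none", "cracked", "over_cured",
                                      "under_cured")))
  crack_mask <- NULL
  rim_idx <- NULL
  alpha <- 1
  if (spec$defect == "over_cured") {
    delta <- stats::runif(1, 0.05, 0.15)
    set.seed(spec$seed)
    delta <- min(max(delta + stats::runif(1, -0.015, 0.015), 0.05), 0.15)
    base_mask <- msk(1)
    mask <- msk(1 + delta)
    rim_idx <- which(mask & !base_mask)
  } else if (spec$defect == "under_cured") {
    delta <- stats::runif(1, 0.10, 0.18)
    k <- sample(1:3, 1)
    angles <- stats::runif(k, 0, 2 * pi)
    radii <- stats::runif(k, 0.10, 0.20) * min_dim_px
    alpha <- stats::runif(1, 0.40, 0.60)
    set.seed(spec$seed)
    delta <- min(max(delta + stats::runif(1, -0.015, 0.015), 0.10), 0.18)
    angles <- angles + stats::rnorm(k, 0, 2 * pi / 180)
    alpha <- min(max(alpha + stats::runif(1, -0.04, 0.04), 0.35), 0.65)
    mask <- msk(1 - delta)
    for (j in seq_len(k)) {
      r <- .edge_radius(spec, angles[j], scale = 1 - delta)
      ctr <- r * c(cos(angles[j]), sin(angles[j]))
      mask <- mask & !(((X - ctr[1])^2 + (Y - ctr[2])^2) <= radii[j]^2)
    }
  } else {
    mask <- msk(1)
  }
  if (spec$defect == "cracked") {
    k <- sample(1:3, 1)
    design <- vector("list", k)
    for (j in seq_len(k)) {
      t1 <- stats::runif(1, 0, 2 * pi)
      t2 <- t1 + pi + stats::runif(1, -0.5, 0.5)
      p1 <- .edge_radius(spec, t1) * c(cos(t1), sin(t1))
      p2 <- .edge_radius(spec, t2) * c(cos(t2), sin(t2))
      m <- 8L
      tt <- seq(0, 1, length.out = m + 1L)
      pts <- cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
      span <- sqrt(sum((p2 - p1)^2))
      perp <- c(-(p2[2] - p1[2]), p2[1] - p1[1]) / max(span, 1e-9)
      jit <- stats::rnorm(m + 1L, 0, 0.05 * span)
      jit[c(1L, m + 1L)] <- 0
      pts[, 1] <- pts[, 1] + jit * perp[1]
      pts[, 2] <- pts[, 2] + jit * perp[2]
      hw <- max(stats::runif(1, 0.01, 0.03) * min_dim_px / 2, 0.75)
      design[[j]] <- list(pts = pts, hw = hw, span = span)
    }
    set.seed(spec$seed)
    crack_mask <- matrix(FALSE, n, n)
    for (j in seq_len(k)) {
      pts <- design[[j]]$pts
      hw <- design[[j]]$hw
      pts <- pts + matrix(stats::rnorm(length(pts), 0, 0.012 * design[[j]]$span),
                          nrow(pts), 2)
      # rasterize in the canvas frame (distances are rotation-invariant),
      # restricted to the polyline's bounding window for speed
      ptsc <- cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
                    pts[, 1] * sin(th) + pts[, 2] * cos(th))
      ci <- range(which(xv >= min(ptsc[, 1]) - hw - 1 & xv <= max(ptsc[, 1]) + hw + 1))
      ri <- range(which(yv >= min(ptsc[, 2]) - hw - 1 & yv <= max(ptsc[, 2]) + hw + 1))
      rs <- ri[1]:ri[2]; cs <- ci[1]:ci[2]
      Xw <- matrix(xv[cs], length(rs), length(cs), byrow = TRUE)
      Yw <- matrix(yv[rs], length(rs), length(cs), byrow = FALSE)
      crack_mask[rs, cs] <- crack_mask[rs, cs] | .polyline_mask(Xw, Yw, ptsc, hw)
    }
    crack_mask <- crack_mask & mask
  }
  set.seed(spec$seed + 1L)  # per-image stream: sensor noise

  shade <- .shade_field(n)

  fidx <- which(mask)
  # layer-line texture, evaluated on the silhouette only, in the print frame
  lt <- spec$layer_texture
  tex_f <- 1 - (lt$amplitude / 255) * (0.5 + 0.5 * sin(2 * pi * Y[fidx] / lt$spacing_px))
  if (g$form == "capsule") {
    # the seam where the two capsule halves join: a darker band across the
    # body at mid-length
    seam_hw <- 0.015 * g$length_mm * g$px_per_mm
    seam <- abs(X[fidx]) <= seam_hw
    tex_f[seam] <- tex_f[seam] * 0.70
  }
  shade_f <- shade[fidx]
  bgmat <- spec$background_shade * shade
  bg_f <- bgmat[fidx]
  cidx <- if (!is.null(crack_mask)) which(crack_mask) else NULL
  if (!is.null(cidx)) crack_shade <- shade[cidx] *
      (1 - (lt$amplitude / 255) * (0.5 + 0.5 * sin(2 * pi * Y[cidx] / lt$spacing_px)))
  if (!is.null(rim_idx)) {
    rim_tex <- 1 - (lt$amplitude / 255) * (0.5 + 0.5 * sin(2 * pi * Y[rim_idx] / lt$spacing_px))
    rim_shade <- shade[rim_idx]
    rim_bg <- bgmat[rim_idx]
  }

  out <- array(0, dim = c(n, n, 3))
  noise <- NULL
  if (spec$noise_sd > 0 && spec$chroma_locked)
    noise <- stats::rnorm(n * n, 0, spec$noise_sd)
  for (ch in 1:3) {
    fg_f <- spec$base_color[ch] * tex_f * shade_f
    plane <- bgmat
    plane[fidx] <- if (alpha < 1) alpha * fg_f + (1 - alpha) * bg_f else fg_f
    if (!is.null(rim_idx)) {
      # darkened, partially transparent rim of excess resin
      plane[rim_idx] <- 0.55 * spec$base_color[ch] * rim_tex * rim_shade +
        0.20 * rim_bg
    }
    if (!is.null(cidx)) plane[cidx] <- 0.15 * spec$base_color[ch] * crack_shade
    if (spec$noise_sd > 0) {
      if (spec$chroma_locked) plane <- plane + noise
      else plane <- plane + stats::rnorm(n * n, 0, spec$noise_sd)
    }
    plane[plane < 0] <- 0
    plane[plane > 255] <- 255
    out[, , ch] <- floor(plane + 0.5)
  }
  storage.mode(out) <- "integer"

  img <- qc_image(out, label = spec$quality, defect = spec$defect,
                  source = "virtual",
                  digest = sprintf("%s/%s/%s/seed=%d", g$form, spec$quality,
                                   spec$defect, spec$seed))
  attr(img, "masks") <- list(silhouette = mask, crack = crack_mask)
  img
}

# Even split of n_bad across the three defect subtypes; any remainder goes
# to 'cracked' (reproducibly fixes the one extra bad image of a 100-image
# bad set as a cracked print).
.defect_schedule <- function(n_bad) {
  base <- n_bad %/% 3L
  rem <- n_bad %% 3L
  c(rep("cracked", base + rem),
    rep("over_cured", base),
    rep("under_cured", base))
}

# Training palette swept across the loop: tan -> yellow -> orange ->
# off-white resin bodies, photographed against a dark enclosure. Together
# with the near-black background this spans the black/yellow/orange/white
# gamut typical of rendered resin prints.
.palette_color <- function(t, sat_jitter = 1) {
  anchors <- rbind(c(115, 102, 88),
                   c(205, 165, 55),
                   c(215, 130, 45),
                   c(210, 205, 196))
  pos <- c(0, 1 / 3, 2 / 3, 1)
  i <- findInterval(t, pos, rightmost.closed = TRUE)
  i <- max(1L, min(i, 3L))
  f <- (t - pos[i]) / (pos[i + 1] - pos[i])
  col <- (1 - f) * anchors[i, ] + f * anchors[i + 1, ]
  lum <- mean(col)
  col <- lum + sat_jitter * (col - lum)  # chroma scaling about the gray axis
  pmin(pmax(col, 0), 255)
}

#' Generate the virtual training corpus for one dosage form
#'
#' Produces `n_good` defect-free and `n_bad` defective renders. Bad images are
#' split as evenly as possible across the three defect subtypes with any
#' remainder assigned to `'cracked'`; base colors are swept systematically
#' across each loop (hue ramp with small seeded saturation jitter). Fully
#' deterministic under `seed`.
#'
#' @param form `"capsule"`, `"tablet"` or `"film"`.
#' @param n_good,n_bad class counts (`n_bad >= 3` to cover the taxonomy).
#' @param seed root seed; image `i` renders with seed `seed + i`.
#' @param canvas_px canvas side (default 512).
#' @param px_per_mm raster scale passed to [form_geometry()].
#' @param transform optional function applied to each [qc_image] before it is
#'   stored (e.g. grayscale + resize), which keeps memory bounded for large
#'   corpora at full canvas resolution.
#' @return a [qc_dataset] of `n_good + n_bad` virtual images.
#' @export
generate_training_set <- function(form, n_good = 100L, n_bad = 100L, seed = 1L,
                                  canvas_px = 512L, px_per_mm = NULL,
                                  transform = NULL) {
  if (n_good < 1L) stop("n_good must be >= 1", call. = FALSE)
  if (n_bad < 3L) stop("n_bad must be >= 3 to cover all defect subtypes", call. = FALSE)
  geom <- form_geometry(form, canvas_px = canvas_px, px_per_mm = px_per_mm)
  defects <- c(rep("none", n_good), .defect_schedule(n_bad))
  qualities <- ifelse(defects == "none", "good", "bad")
  ngood_t <- if (n_good > 1) (seq_len(n_good) - 1) / (n_good - 1) else 0.5
  nbad_t <- if (n_bad > 1) (seq_len(n_bad) - 1) / (n_bad - 1) else 0.5
  tt <- c(ngood_t, nbad_t)

  set.seed(seed)
  n <- n_good + n_bad
  # scene constants for the whole corpus: the loop varies colors and noise
  # over a fixed scene, so the layer texture is drawn once
  spac <- stats::runif(1, 6, 10)
  amp <- stats::runif(1, 20, 40)
  sat <- stats::runif(n, 0.85, 1.15)
  bgs <- stats::runif(n, 18, 45)

  items <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- render_spec(
      geometry = geom,
      quality = qualities[i],
      defect = defects[i],
      base_color = .palette_color(tt[i], sat[i]),
      layer_texture = list(spacing_px = spac, amplitude = amp),
      background_shade = bgs[i],
      noise_sd = 5,
      seed = seed + i,
      defect_seed = seed + 7001L
    )
    items[[i]] <- render_form(sp)
    if (!is.null(transform)) items[[i]] <- transform(items[[i]])
  }
  qc_dataset(items, form = form, seed = seed, role = "train")
}

#' Generate the domain-shifted photograph-like test corpus
#'
#' A synthetic stand-in for smartphone photographs of physical SLA prints.
#' Relative to the virtual training corpus it applies a deliberate domain
#' shift: a near-grayscale palette (per-pixel channel spread at most 15
#' intensity units before noise), a canvas at least twice the training canvas
#' (which drives a severalfold PNG byte-size gap), luminance-locked
#' sensor noise, and random in-plane pose jitter. Class balance is 50:50 with
#' the bad half split in thirds across defect subtypes (remainder to
#' 'cracked').
#'
#' @param form dosage form.
#' @param n total images; must be even and at least 6.
#' @param seed root seed.
#' @param canvas_px canvas side (default 1024, twice the training default).
#' @param transform optional per-image function applied before storage, as in
#'   [generate_training_set()].
#' @return a [qc_dataset] of `n` pseudo-real images.
#' @export
generate_pseudo_real_set <- function(form, n = 200L, seed = 1L,
                                     canvas_px = 1024L, transform = NULL) {
  if (n %% 2L != 0L) stop("n must be even for a 50:50 class balance", call. = FALSE)
  if (n < 6L) stop("n must be >= 6", call. = FALSE)
  geom <- form_geometry(form, canvas_px = canvas_px)
  n_good <- n %/% 2L
  defects <- c(rep("none", n_good), .defect_schedule(n - n_good))
  qualities <- ifelse(defects == "none", "good", "bad")

  set.seed(seed)
  # one photographic scene per corpus: fixed layer texture, varying print
  # colors, pose jitter and sensor noise
  spac <- stats::runif(1, 12, 20)
  amp <- stats::runif(1, 20, 40)
  shadev <- stats::runif(n, 95, 195)
  chroma <- matrix(stats::runif(3 * n, -5, 5), n, 3)
  bgs <- stats::runif(n, 15, 48)
  rot <- stats::runif(n, -2, 2)
  offx <- stats::runif(n, -0.01, 0.01) * canvas_px
  offy <- stats::runif(n, -0.01, 0.01) * canvas_px

  items <- vector("list", n)
  for (i in seq_len(n)) {
    col <- pmin(pmax(shadev[i] + chroma[i, ], 0), 255)
    sp <- render_spec(
      geometry = geom,
      quality = qualities[i],
      defect = defects[i],
      base_color = col,
      layer_texture = list(spacing_px = spac, amplitude = amp),
      background_shade = bgs[i],
      noise_sd = 6,
      chroma_locked = TRUE,
      rotation_deg = rot[i],
      offset_px = c(offx[i], offy[i]),
      seed = seed + 100000L + i,
      defect_seed = seed + 7002L
    )
    img <- render_form(sp)
    img$source <- "pseudo_real"
    if (!is.null(transform)) img <- transform(img)
    items[[i]] <- img
  }
  qc_dataset(items, form = form, seed = seed, role = "test")
}

#' Out-of-distribution distractor specification
#'
#' @param kind one of `"background"` (uniform dark canvas with shade jitter),
#'   `"noise"` (i.i.d. uniform pixels), or a filled shape: `"triangle"`,
#'   `"oblong"`, `"circle"`, `"diamond"` at random pose.
#' @param n number of images (>= 1).
#' @param canvas_px canvas side.
#' @param seed root seed.
#' @return an object of class `ood_spec`.
#' @export
ood_spec <- function(kind = c("background", "noise", "triangle", "oblong",
                              "circle", "diamond"),
                     n = 200L, canvas_px = 512L, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  structure(list(kind = kind, n = as.integer(n),
                 canvas_px = as.integer(canvas_px), seed = as.integer(seed)),
            class = "ood_spec")
}

# mask for one OOD shape centered at (cx, cy) in pixel coordinates
.ood_shape_mask <- function(kind, X, Y, size, theta, aspect) {
  Xr <- X * cos(theta) + Y * sin(theta)
  Yr <- -X * sin(theta) + Y * cos(theta)
  switch(kind,
         circle = (Xr^2 + Yr^2) <= size^2,
         oblong = {
           a <- size * aspect; b <- size
           core <- pmax(abs(Xr) - (a - b), 0)
           core^2 + Yr^2 <= b^2
         },
         diamond = (abs(Xr) / (size * aspect) + abs(Yr) / size) <= 1,
         triangle = {
           # equilateral triangle, circumradius = size
           v <- sapply(0:2, function(k) size * c(cos(pi / 2 + 2 * pi * k / 3),
                                                 sin(pi / 2 + 2 * pi * k / 3)))
           inside <- matrix(TRUE, nrow(X), ncol(X))
           for (k in 1:3) {
             p <- v[, k]; q <- v[, k %% 3 + 1]
             inside <- inside & ((q[1] - p[1]) * (Yr - p[2]) -
                                 (q[2] - p[2]) * (Xr - p[1]) <= 0)
           }
           inside
         })
}

#' Generate out-of-distribution distractor images
#'
#' None of the produced images depicts a dosage form; every image is labeled
#' `'bad'` (the correct call for a QC model is to reject them all).
#'
#' @param spec an [ood_spec].
#' @param transform optional per-image function applied before storage, as in
#'   [generate_training_set()].
#' @return a [qc_dataset] of `spec$n` images with source `"ood"`.
#' @export
generate_ood_set <- function(spec, transform = NULL) {
  if (!inherits(spec, "ood_spec")) stop("`spec` must be an ood_spec", call. = FALSE)
  n <- spec$canvas_px
  items <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    set.seed(spec$seed + i)
    if (spec$kind == "background") {
      shade <- stats::runif(1, 5, 45)
      plane <- matrix(shade + stats::rnorm(n * n, 0, 2), n, n)
      plane[plane < 0] <- 0; plane[plane > 255] <- 255
      px <- array(floor(plane + 0.5), dim = c(n, n, 3))
    } else if (spec$kind == "noise") {
      px <- array(floor(stats::runif(3 * n * n, 0, 256)), dim = c(n, n, 3))
      px[px > 255] <- 255
    } else {
      idx <- seq_len(n) - 0.5
      ctr <- stats::runif(2, 0.28, 0.72) * n
      X <- matrix(idx, n, n, byrow = TRUE) - ctr[1]
      Y <- matrix(idx, n, n, byrow = FALSE) - ctr[2]
      size <- stats::runif(1, 0.05, 0.34) * n
      theta <- stats::runif(1, 0, 2 * pi)
      aspect <- stats::runif(1, 1.3, 3.2)
      mask <- .ood_shape_mask(spec$kind, X, Y, size, theta, aspect)
      bg <- stats::runif(1, 15, 48)
      fill <- stats::runif(1, 80, 200)
      plane0 <- matrix(bg, n, n)
      plane0[mask] <- fill
      px <- array(0, dim = c(n, n, 3))
      noise <- matrix(stats::rnorm(n * n, 0, 4), n, n)
      for (ch in 1:3) {
        plane <- plane0 + noise
        plane[plane < 0] <- 0; plane[plane > 255] <- 255
        px[, , ch] <- floor(plane + 0.5)
      }
    }
    storage.mode(px) <- "integer"
    items[[i]] <- qc_image(px, label = "bad", defect = "none",
                           source = "ood",
                           digest = sprintf("ood/%s/seed=%d", spec$kind,
                                            spec$seed + i))
    if (!is.null(transform)) items[[i]] <- transform(items[[i]])
  }
  qc_dataset(items, form = NA_character_, seed = spec$seed, role = "ood",
             kind = spec$kind)
}

#' Matched-geometry OOD shape for a dosage form
#'
#' The distractor whose outline most resembles the form: oblong for capsules,
#' circle for tablets, diamond for films.
#'
#' @param form dosage form.
#' @return character scalar shape kind.
#' @export
matched_ood_shape <- function(form) {
  switch(match.arg(form, c("capsule", "tablet", "film")),
         capsule = "oblong", tablet = "circle", film = "diamond")
}

#' Default OOD test battery for a form
#'
#' Background, noise, a generic shape (triangle) and the matched-geometry
#' shape.
#'
#' @param form dosage form.
#' @return character vector of 4 kinds.
#' @export
ood_kinds <- function(form) {
  c("background", "noise", "triangle", matched_ood_shape(form))
}
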