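# Synthetic quadrat imagery with known ground truth. The generator aims at
# the statistical structure of paddy quadrat photographs — a textured green
# canopy, elongated bright yellow ear blobs that may touch and overlap,
# varying illumination, an optional red quadrat frame — not photorealism.
# Every ear carries exactly one annotation point near its centre, so count
# conservation (count == number of points) holds by construction.

#' Configuration for the synthetic field generator
#'
#' @param image_size integer (H, W), both >= 32.
#' @param count_law ears per image: `list("fixed", n)`,
#'   `list("uniform", min, max)` or `list("poisson", lambda)`.
#' @param ear_length,ear_width pixel ranges (min, max) of the ear ellipse
#'   major/minor full axes.
#' @param orientation orientation range in radians (default all).
#' @param overlap_fraction probability in `[0, 1]` that an ear is placed
#'   touching a previously placed ear; at 0 ears are kept pairwise
#'   non-adjacent (a one-pixel gap, so 8-connected blobs stay distinct).
#' @param illumination brightness multiplier range.
#' @param red_frame draw a red quadrat frame (all ears then lie strictly
#'   inside the inner frame boundary).
#' @param frame_thickness frame thickness in pixels.
#' @param frame_angle frame rotation in radians (0 = axis-aligned).
#' @param leaves number of broad bright leaf blades to draw under the ears
#'   (0 = none); used by the classical-baseline test imagery.
#' @param color_cast multiplier applied to the red channel (quality level C
#'   imagery is red-shifted).
#' @param noise_sd additive Gaussian pixel noise scale.
#' @param seed integer master seed.
#' @return list of class `field_sim_config`.
#' @export
field_sim_config <- function(image_size = c(96, 96),
                             count_law = list("uniform", 3, 12),
                             ear_length = c(10, 16), ear_width = c(3, 5),
                             orientation = c(0, pi),
                             overlap_fraction = 0.2,
                             illumination = c(0.75, 1.15),
                             red_frame = FALSE, frame_thickness = 4,
                             frame_angle = 0,
                             leaves = 0, color_cast = 1,
                             noise_sd = 0.03, seed = 1) {
  if (length(image_size) != 2 || any(image_size < 32))
    stopf("image_size must be (H, W) with both >= 32")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must be in [0, 1]")
  law <- count_law[[1]]
  if (!law %in% c("fixed", "uniform", "poisson"))
    stopf("count_law must be fixed, uniform or poisson")
  structure(list(image_size = as.integer(image_size), count_law = count_law,
                 ear_length = ear_length, ear_width = ear_width,
                 orientation = orientation,
                 overlap_fraction = overlap_fraction,
                 illumination = illumination,
                 red_frame = isTRUE(red_frame),
                 frame_thickness = frame_thickness,
                 frame_angle = frame_angle,
                 leaves = leaves, color_cast = color_cast,
                 noise_sd = noise_sd, seed = seed),
            class = "field_sim_config")
}

#' Preset configurations mirroring the three field-image quality levels
#'
#' "A" = clear, low noise; "B" = noisy; "C" = red-shifted colour cast.
#' @param level "A", "B" or "C".
#' @param ... overrides passed to [field_sim_config()].
#' @export
field_quality_preset <- function(level = c("A", "B", "C"), ...) {
  level <- match.arg(level)
  base <- switch(level,
    A = list(noise_sd = 0.02, illumination = c(0.9, 1.1), color_cast = 1),
    B = list(noise_sd = 0.08, illumination = c(0.6, 1.2), color_cast = 1),
    C = list(noise_sd = 0.05, illumination = c(0.7, 1.1), color_cast = 1.35))
  do.call(field_sim_config, utils::modifyList(base, list(...)))
}

draw_count <- function(law) {
  switch(law[[1]],
    fixed = law[[2]],
    uniform = sample(law[[2]]:law[[3]], 1),
    poisson = stats::rpois(1, law[[2]]))
}

# Elliptical support mask: centre (cy, cx), full axes (len, wid), angle th.
ellipse_mask <- function(h, w, cy, cx, len, wid, th) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (len / 2))^2 + (v / (wid / 2))^2 <= 1
}

# Low-frequency multiplicative texture: a small random grid upsampled
# bilinearly, centred on 1.
texture_field <- function(h, w, cells = 8, amp = 0.25) {
  g <- matrix(stats::runif(cells * cells, 1 - amp, 1 + amp), cells, cells)
  resize_bilinear(g, h, w)
}

# Square frame membership in rotated frame coordinates.
frame_mask <- function(h, w, cy, cx, half_inner, half_outer, th) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  m <- pmax(abs(u), abs(v))
  m > half_inner & m <= half_outer
}

# True inner-edge corners of the frame, clockwise from top-left, (row, col).
frame_inner_corners <- function(h, w, half_inner, th) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  base <- rbind(c(-half_inner, -half_inner), c(-half_inner, half_inner),
                c(half_inner, half_inner), c(half_inner, -half_inner)) # (v=row, u=col)
  u <- base[, 2] * cos(th) - base[, 1] * sin(th)
  v <- base[, 2] * sin(th) + base[, 1] * cos(th)
  cbind(row = cy + v, col = cx + u)
}

#' Render one synthetic quadrat image
#'
#' Deterministic given `config$seed`. The returned [annotated_image()]
#' carries generator ground truth in `$meta`: `ear_masks` (list of logical
#' supports), and `frame_corners` (true inner-edge corners) when a frame is
#' drawn.
#'
#' @param config a [field_sim_config()].
#' @param image_id id for the produced image.
#' @param keep_masks keep the per-ear support masks in `$meta` (default
#'   TRUE; switch off for large batches).
#' @export
simulate_image <- function(config, image_id = "sim", keep_masks = TRUE) {
  stopifnot(inherits(config, "field_sim_config"))
  with_seed(config$seed,
            render_field(config, image_id, keep_masks))
}

render_field <- function(config, image_id, keep_masks) {
  h <- config$image_size[1]; w <- config$image_size[2]
  if (config$ear_length[2] >= min(h, w) - 4)
    stopf("ear geometry (length up to %g px) cannot fit in a %d x %d image",
          config$ear_length[2], h, w)

  # --- background: textured green canopy
  px <- array(0, c(h, w, 3))
  tex <- texture_field(h, w)
  px[, , 1] <- 0.13 * tex
  px[, , 2] <- 0.38 * texture_field(h, w)
  px[, , 3] <- 0.10 * tex

  meta <- list()
  inner_limit <- NULL
  if (config$red_frame) {
    # the rotated outer square must fit fully inside the raster
    th0 <- abs(config$frame_angle)
    half_outer <- (min(h, w) / 2 - 2) / (cos(th0) + sin(th0))
    half_inner <- half_outer - config$frame_thickness
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    fm <- frame_mask(h, w, cy, cx, half_inner, half_outer, config$frame_angle)
    px[, , 1][fm] <- 0.85
    px[, , 2][fm] <- 0.08
    px[, , 3][fm] <- 0.08
    meta$frame_corners <- frame_inner_corners(h, w, half_inner, config$frame_angle)
    meta$half_inner <- half_inner
    # ears stay strictly inside the inner boundary with a safety margin
    inner_limit <- half_inner - 1
  }

  # --- leaves: broad bright blades (for classical-baseline imagery)
  leaf_mask_all <- matrix(FALSE, h, w)
  if (config$leaves > 0) for (l in seq_len(config$leaves)) {
    lm <- ellipse_mask(h, w,
                       cy = stats::runif(1, h * 0.2, h * 0.8),
                       cx = stats::runif(1, w * 0.2, w * 0.8),
                       len = stats::runif(1, 0.5, 0.8) * min(h, w),
                       wid = stats::runif(1, 12, 18),
                       th = stats::runif(1, 0, pi))
    if (!is.null(inner_limit)) {
      keep <- frame_mask(h, w, (h + 1) / 2, (w + 1) / 2, -1, inner_limit,
                         config$frame_angle)
      lm <- lm & keep
    }
    shade <- stats::runif(1, 0.85, 1.05)
    px[, , 1][lm] <- 0.42 * shade
    px[, , 2][lm] <- 0.62 * shade
    px[, , 3][lm] <- 0.30 * shade
    leaf_mask_all <- leaf_mask_all | lm
  }

  # --- ears
  n <- draw_count(config$count_law)
  ear_masks <- list()
  points <- matrix(integer(0), ncol = 2)
  occupied <- matrix(FALSE, h, w)      # union of placed ears
  blocked <- matrix(FALSE, h, w)       # occupied dilated by 1 (adjacency)
  placed <- 0
  attempts <- 0
  while (placed < n && attempts < 200 * n + 200) {
    attempts <- attempts + 1
    len <- stats::runif(1, config$ear_length[1], config$ear_length[2])
    wid <- stats::runif(1, config$ear_width[1], config$ear_width[2])
    th <- stats::runif(1, config$orientation[1], config$orientation[2])
    margin <- len / 2 + 2
    if (is.null(inner_limit)) {
      cy <- stats::runif(1, margin, h - margin)
      cx <- stats::runif(1, margin, w - margin)
    } else {
      lim <- inner_limit - margin
      if (lim <= 0) stopf("ear geometry cannot fit inside the quadrat frame")
      cy <- (h + 1) / 2 + stats::runif(1, -lim, lim)
      cx <- (w + 1) / 2 + stats::runif(1, -lim, lim)
    }
    em <- ellipse_mask(h, w, cy, cx, len, wid, th)
    if (!any(em)) next
    want_overlap <- placed > 0 && stats::runif(1) < config$overlap_fraction
    touches <- any(em & blocked)
    if (!want_overlap && touches) next
    if (want_overlap && placed > 0 && !touches) next

    # annotation point: centre jittered by <= 20% of the minor axis,
    # re-drawn until it falls on the ear support and on a free pixel
    pt <- NULL
    for (try in 1:30) {
      jr <- round(cy + stats::runif(1, -0.2, 0.2) * wid)
      jc <- round(cx + stats::runif(1, -0.2, 0.2) * wid)
      jr <- min(max(jr, 1), h); jc <- min(max(jc, 1), w)
      if (em[jr, jc] && (nrow(points) == 0 ||
                         !any(points[, 1] == jr & points[, 2] == jc))) {
        pt <- c(jr, jc); break
      }
    }
    if (is.null(pt)) next

    shade <- stats::runif(1, 0.9, 1.1)
    grain <- matrix(stats::runif(h * w, 0.8, 1.2), h, w)
    px[, , 1][em] <- (0.78 * shade * grain)[em]
    px[, , 2][em] <- (0.70 * shade * grain)[em]
    px[, , 3][em] <- (0.34 * shade * grain)[em]

    if (keep_masks) ear_masks[[placed + 1]] <- em
    points <- rbind(points, pt)
    occupied <- occupied | em
    blocked <- blocked | dilate1(em)
    placed <- placed + 1
  }
  if (placed < n)
    warnf("placed %d of %d ears before giving up (image too crowded)", placed, n)

  # --- illumination, colour cast, noise
  illum <- stats::runif(1, config$illumination[1], config$illumination[2])
  grad <- matrix(seq(0.95, 1.05, length.out = w), h, w, byrow = TRUE)
  for (k in 1:3) px[, , k] <- px[, , k] * illum * grad
  px[, , 1] <- px[, , 1] * config$color_cast
  if (config$noise_sd > 0)
    px <- px + array(stats::rnorm(h * w * 3, 0, config$noise_sd), c(h, w, 3))
  px <- clip01(px)

  meta$ear_masks <- if (keep_masks) ear_masks else NULL
  meta$leaf_mask <- if (config$leaves > 0) leaf_mask_all else NULL
  annotated_image(px, points, image_id = image_id, meta = meta)
}

# binary dilation by one pixel (8-neighbourhood), pure shifts
dilate1 <- function(m) {
  out <- m
  for (s in neighbor_shifts(8)) out <- out | shift_mat(m * 1, s[1], s[2], fill = 0) > 0
  out
}

#' Render a batch of synthetic images
#'
#' Per-image seeds are derived from the master seed, so item i is
#' reproducible independently of the batch size.
#'
#' @param config a [field_sim_config()]; its `seed` is the master seed.
#' @param n_images number of images (>= 1).
#' @param out optional directory: when given, images, point masks and
#'   `counts.csv` are written in the [write_dataset()] layout.
#' @param id_prefix image-id prefix.
#' @param keep_masks keep per-ear supports in each image's `$meta`.
#' @return an [ear_dataset()].
#' @export
simulate_dataset <- function(config, n_images, out = NULL, id_prefix = "sim",
                             keep_masks = FALSE) {
  stopifnot(inherits(config, "field_sim_config"))
  if (n_images < 1) stopf("n_images must be >= 1")
  seeds <- derive_seeds(config$seed, n_images)
  fmt <- sprintf("%%s%%0%dd", max(4, nchar(n_images)))
  imgs <- lapply(seq_len(n_images), function(i) {
    ci <- config; ci$seed <- seeds[i]
    simulate_image(ci, image_id = sprintf(fmt, id_prefix, i),
                   keep_masks = keep_masks)
  })
  ds <- ear_dataset(imgs)
  if (!is.null(out)) write_dataset(ds, out)
  ds
}
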