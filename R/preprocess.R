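# Quadrat preprocessing: locate the red frame by ray casting from the
# image centre, fit one line per side through the two inner-edge hit
# points, intersect adjacent lines to get the corners, then stretch the
# enclosed quadrilateral to a full rectangle by a perspective warp.
# Annotation points ride along under the same homography.

#' Red-pixel classifier used by frame detection
#'
#' HSV window around hue 0/360 degrees with minimum saturation and value.
#' @param pixels H x W x 3 array.
#' @param hue_window degrees either side of red (default 20).
#' @param min_sat,min_val thresholds in `[0, 1]`.
#' @return logical H x W matrix.
#' @export
red_mask <- function(pixels, hue_window = 20, min_sat = 0.45, min_val = 0.25) {
  d <- dim(pixels)
  hsv <- grDevices::rgb2hsv(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
                            as.vector(pixels[, , 3]), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  m <- (hue <= hue_window | hue >= 360 - hue_window) &
    hsv[2, ] >= min_sat & hsv[3, ] >= min_val
  matrix(m, d[1], d[2])
}

# Walk from (r0, c0) in direction (dr, dc) in quarter-pixel steps until a
# red pixel; returns the sub-pixel edge estimate (half a step before the
# first red sample) or NULL when the ray exits the image.
cast_ray <- function(red, r0, c0, dr, dc, step = 0.25) {
  h <- nrow(red); w <- ncol(red)
  r <- r0; c <- c0
  repeat {
    r <- r + dr * step; c <- c + dc * step
    ri <- round(r); ci <- round(c)
    if (ri < 1 || ri > h || ci < 1 || ci > w) return(NULL)
    if (red[ri, ci]) return(c(r - dr * step / 2, c - dc * step / 2))
  }
}

# Line through two (row, col) points as coefficients a*row + b*col + d = 0.
line_through <- function(p, q) {
  a <- q[2] - p[2]; b <- -(q[1] - p[1])
  c(a, b, -(a * p[1] + b * p[2]))
}

intersect_lines <- function(l1, l2) {
  det <- l1[1] * l2[2] - l2[1] * l1[2]
  if (abs(det) < 1e-9) stopf("frame detection failed: parallel side lines")
  c(row = (-l1[3] * l2[2] + l2[3] * l1[2]) / det,
    col = (-l1[1] * l2[3] + l2[1] * l1[3]) / det)
}

#' Detect the inner corners of a red quadrat frame
#'
#' Two rays per side are emitted from points offset +-25% of the image
#' height/width from the centre, outward along the four cardinal
#' directions; each ray stops at the first red sample (quarter-pixel
#' stepping). The two hits per side define the side's inner-edge line;
#' adjacent lines intersect in the corners (sub-pixel, clockwise from
#' top-left). The wide ray baseline keeps the hit quantisation error from
#' being amplified at the corners.
#'
#' @param pixels H x W x 3 array or [annotated_image()].
#' @param offset_frac ray offset as a fraction of image size (default 0.25).
#' @param ... thresholds passed to [red_mask()].
#' @return object of class `quad_corners`: 4 x 2 matrix (row, col), rows
#'   ordered top-left, top-right, bottom-right, bottom-left.
#' @export
detect_red_frame <- function(pixels, offset_frac = 0.25, ...) {
  if (is_annotated_image(pixels)) pixels <- pixels$pixels
  red <- red_mask(pixels, ...)
  if (!any(red)) stopf("frame not found: no red pixels in image")
  h <- nrow(red); w <- ncol(red)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  oy <- offset_frac * h; ox <- offset_frac * w

  hit <- function(r0, c0, dr, dc) {
    p <- cast_ray(red, r0, c0, dr, dc)
    if (is.null(p)) stopf("frame not found: a ray exited the image without hitting red")
    p
  }
  top    <- list(hit(cy, cx - ox, -1, 0), hit(cy, cx + ox, -1, 0))
  bottom <- list(hit(cy, cx - ox,  1, 0), hit(cy, cx + ox,  1, 0))
  left   <- list(hit(cy - oy, cx, 0, -1), hit(cy + oy, cx, 0, -1))
  right  <- list(hit(cy - oy, cx, 0,  1), hit(cy + oy, cx, 0,  1))

  lt <- line_through(top[[1]], top[[2]])
  lb <- line_through(bottom[[1]], bottom[[2]])
  ll <- line_through(left[[1]], left[[2]])
  lr <- line_through(right[[1]], right[[2]])

  corners <- rbind(intersect_lines(lt, ll), intersect_lines(lt, lr),
                   intersect_lines(lb, lr), intersect_lines(lb, ll))
  rownames(corners) <- c("tl", "tr", "br", "bl")
  colnames(corners) <- c("row", "col")
  if (!is_convex_quad(corners)) stopf("frame detection failed: corners are not convex")
  structure(corners, class = c("quad_corners", "matrix"))
}

is_convex_quad <- function(corners) {
  cr <- numeric(4)
  for (i in 1:4) {
    p <- corners[i, ]; q <- corners[i %% 4 + 1, ]; r <- corners[(i + 1) %% 4 + 1, ]
    cr[i] <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
  }
  all(cr > 0) || all(cr < 0)
}

# Homography H (3x3) mapping source (row, col, 1) -> destination, solved
# from 4 correspondences by the direct linear method (8 unknowns).
solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    r <- src[i, 1]; c <- src[i, 2]; R <- dst[i, 1]; C <- dst[i, 2]
    A[2 * i - 1, ] <- c(r, c, 1, 0, 0, 0, -r * R, -c * R); b[2 * i - 1] <- R
    A[2 * i, ]     <- c(0, 0, 0, r, c, 1, -r * C, -c * C); b[2 * i] <- C
  }
  hvec <- tryCatch(solve(A, b),
                   error = function(e) stopf("degenerate corners: %s", conditionMessage(e)))
  matrix(c(hvec, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, pts) {
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' Rectify a quadrat to a full rectangle
#'
#' Perspective warp mapping the quadrilateral `corners` to the full
#' `out_size` rectangle (bilinear sampling). Annotation points, when
#' given, are transformed by the same homography.
#'
#' @param pixels H x W x 3 array or [annotated_image()].
#' @param corners [detect_red_frame()] output (or any 4 x 2 (row, col)
#'   matrix ordered tl, tr, br, bl).
#' @param out_size integer (H, W) of the output; default the input size.
#' @param points optional points to transport (taken from the
#'   `annotated_image` automatically).
#' @return an [annotated_image()] when points are available, else an array.
#' @export
rectify <- function(pixels, corners, out_size = NULL, points = NULL) {
  img <- NULL
  if (is_annotated_image(pixels)) {
    img <- pixels; points <- if (is.null(points)) img$points else points
    pixels <- img$pixels
  }
  d <- dim(pixels)
  if (is.null(out_size)) out_size <- d[1:2]
  ho <- out_size[1]; wo <- out_size[2]
  corners <- unclass(corners)
  if (!is_convex_quad(corners)) stopf("degenerate or non-convex corners")
  out_corners <- rbind(c(1, 1), c(1, wo), c(ho, wo), c(ho, 1))
  Hinv <- solve_homography(out_corners, corners)   # output -> input

  og <- cbind(rep(seq_len(ho), times = wo), rep(seq_len(wo), each = ho))
  src <- apply_homography(Hinv, og)
  sr <- pmin(pmax(src[, 1], 1), d[1])
  sc <- pmin(pmax(src[, 2], 1), d[2])
  r0 <- pmin(floor(sr), d[1] - 1); c0 <- pmin(floor(sc), d[2] - 1)
  fr <- sr - r0; fc <- sc - c0
  out <- array(0, c(ho, wo, 3))
  for (k in 1:3) {
    ch <- pixels[, , k]
    v <- ch[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
         ch[cbind(r0 + 1, c0)] * fr * (1 - fc) +
         ch[cbind(r0, c0 + 1)] * (1 - fr) * fc +
         ch[cbind(r0 + 1, c0 + 1)] * fr * fc
    out[, , k] <- matrix(v, ho, wo)
  }
  if (is.null(points) && is.null(img)) return(out)
  Hfwd <- solve_homography(corners, out_corners)   # input -> output
  pts <- as_points(points)
  if (nrow(pts)) {
    tp <- apply_homography(Hfwd, pts)
    keep <- tp[, 1] >= 0.5 & tp[, 1] <= ho + 0.49 & tp[, 2] >= 0.5 & tp[, 2] <= wo + 0.49
    tp <- round(tp[keep, , drop = FALSE])
    tp[, 1] <- pmin(pmax(tp[, 1], 1), ho); tp[, 2] <- pmin(pmax(tp[, 2], 1), wo)
    pts <- as_points(tp)
    pts <- dedupe_points(pts, context = "rectified points")
  }
  annotated_image(out, pts, image_id = if (!is.null(img)) img$image_id else "rectified")
}

#' Resize an annotated image
#'
#' Bilinear raster resampling; points are mapped with the same scale
#' (half-pixel-centre convention) and rounded. Points colliding after
#' rounding are deduplicated with a warning, updating the count.
#'
#' @param image an [annotated_image()].
#' @param scale positive scale factor (e.g. 0.25).
#' @return an [annotated_image()].
#' @export
resize_annotated <- function(image, scale) {
  stopifnot(is_annotated_image(image))
  if (scale <= 0) stopf("scale must be positive")
  d <- dim(image$pixels)
  ho <- round(d[1] * scale); wo <- round(d[2] * scale)
  if (ho < 32 || wo < 32)
    stopf("scale %g shrinks the image to %d x %d (< 32 px)", scale, ho, wo)
  px <- resize_bilinear(image$pixels, ho, wo)
  pts <- image$points
  if (nrow(pts)) {
    tr <- round((pts[, 1] - 0.5) * ho / d[1] + 0.5)
    tc <- round((pts[, 2] - 0.5) * wo / d[2] + 0.5)
    pts <- as_points(cbind(pmin(pmax(tr, 1), ho), pmin(pmax(tc, 1), wo)))
    pts <- dedupe_points(pts, context = "resized points")
  }
  annotated_image(clip01(px), pts, image_id = image$image_id, meta = image$meta["frame_corners"])
}

# ---- augmentation -------------------------------------------------------

flip_image <- function(image) {
  stopifnot(is_annotated_image(image))
  d <- dim(image$pixels)
  px <- image$pixels[, d[2]:1, , drop = FALSE]
  pts <- image$points
  if (nrow(pts)) pts[, 2] <- d[2] + 1L - pts[, 2]
  annotated_image(px, pts, image_id = paste0(image$image_id, "_flip"))
}

rotate90_image <- function(image) {
  stopifnot(is_annotated_image(image))
  d <- dim(image$pixels)
  # 90 degrees counter-clockwise: (r, c) -> (W + 1 - c, r)
  px <- aperm(image$pixels, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  pts <- image$points
  if (nrow(pts)) pts <- cbind(d[2] + 1L - pts[, 2], pts[, 1])
  annotated_image(px, pts, image_id = paste0(image$image_id, "_rot"))
}

#' Flip/rotation augmentation of a dataset
#'
#' `modes = "flip"` returns originals plus one horizontally mirrored copy
#' each (x2); `modes = c("flip", "rotation")` adds one 90-degree
#' counter-clockwise copy each (x3). Annotation points are transported by
#' the same spatial map, so per-image counts are preserved exactly.
#' Augmented ids get deterministic `_flip` / `_rot` suffixes.
#'
#' @param dataset an [ear_dataset()].
#' @param modes subset of `c("flip", "rotation")`.
#' @return an [ear_dataset()].
#' @export
augment <- function(dataset, modes = "flip") {
  dataset <- ear_dataset(dataset)
  if (length(modes) == 0 || !all(modes %in% c("flip", "rotation")))
    stopf("modes must be a non-empty subset of {flip, rotation}")
  out <- unclass(dataset)
  if ("flip" %in% modes) out <- c(out, lapply(dataset, flip_image))
  if ("rotation" %in% modes) out <- c(out, lapply(dataset, rotate90_image))
  ear_dataset(out)
}
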