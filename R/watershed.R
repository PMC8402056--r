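# Marker-seeded watershed used by the split loss. Semantics are defined
# exactly (so that an independent brute-force coding can reproduce them):
#
#   * elevations inside the region are quantized into `nlevels` equal bins
#     over the region's elevation range (a constant region has one bin);
#   * basins start at the seed pixels; the water level L starts at the
#     lowest bin and never recedes; flooding repeats until no unlabeled
#     region pixel touches a basin:
#       - F = unlabeled, non-ridge region pixels with >= 1 basin neighbour
#       - if no member of F has bin <= L, raise L to min(bin over F)
#       - A = members of F with bin <= L update simultaneously from the
#         previous state: a pixel seeing exactly one distinct basin label
#         in its neighbourhood joins that basin; one seeing >= 2 becomes
#         a ridge pixel;
#   * the ridge set is the watershed line E.
#
# Synchronous updates make the result independent of pixel visiting order;
# a basin wavefront advances one ring per iteration at or below the water
# level, so equidistant meeting fronts produce a ridge (two seeds in a
# uniform bar yield the central column).

#' Seeded watershed over an elevation map
#'
#' @param elev numeric matrix of elevations (lower floods first).
#' @param seeds n x 2 matrix of seed pixels (1-based row, col), one basin
#'   each; must lie inside `region`.
#' @param region logical matrix restricting the flood (default: everywhere).
#' @param connectivity 4 or 8 (default 8).
#' @param nlevels number of quantization bins for the elevations.
#' @return list with `basins` (integer matrix, 0 outside/unreached/ridge)
#'   and `ridge` (logical matrix of watershed-line pixels).
#' @export
seeded_watershed <- function(elev, seeds, region = NULL, connectivity = 8,
                             nlevels = 256) {
  stopifnot(is.matrix(elev))
  seeds <- as_points(seeds)
  h <- nrow(elev); w <- ncol(elev)
  if (is.null(region)) region <- matrix(TRUE, h, w)
  check_points_in_bounds(seeds, h, w, "seed")
  if (nrow(seeds) == 0) stopf("at least one seed required")
  if (!all(region[seeds])) stopf("seeds must lie inside the region")

  rng <- range(elev[region])
  bin <- if (rng[2] > rng[1])
    pmin(floor((elev - rng[1]) / (rng[2] - rng[1]) * nlevels), nlevels - 1)
  else matrix(0, h, w)

  state <- matrix(0L, h, w)           # 0 unlabeled, -1 ridge, k>0 basin
  state[seeds] <- seq_len(nrow(seeds))
  shifts <- neighbor_shifts(connectivity)
  level <- -Inf

  repeat {
    # min and max basin label among neighbours (Inf/0 where none)
    basin <- state > 0
    lmin <- matrix(Inf, h, w); lmin[basin] <- state[basin]
    lmax <- matrix(0, h, w);   lmax[basin] <- state[basin]
    nmin <- matrix(Inf, h, w); nmax <- matrix(0, h, w)
    for (s in shifts) {
      nmin <- pmin(nmin, shift_mat(lmin, s[1], s[2], fill = Inf))
      nmax <- pmax(nmax, shift_mat(lmax, s[1], s[2], fill = 0))
    }
    frontier <- region & state == 0L & nmax > 0
    if (!any(frontier)) break
    level <- max(level, min(bin[frontier]))
    active <- frontier & bin <= level
    one <- active & (nmin == nmax)
    many <- active & (nmin != nmax)
    state[one] <- as.integer(nmin[one])
    state[many] <- -1L
  }
  basins <- state; basins[state < 0L] <- 0L
  list(basins = basins, ridge = state == -1L)
}

#' Watershed split boundaries of a probability map
#'
#' For each foreground blob of `argmax(S)` that contains two or more
#' annotation points, a seeded watershed restricted to the blob is run over
#' the topography `-S[, , ear]` (basins grow from high-confidence ear
#' pixels); the inter-basin ridge pixels are collected. Blobs with at most
#' one point contribute nothing.
#'
#' @param S probability map.
#' @param points annotation points.
#' @param labeling optional precomputed [blob_labeling()].
#' @param connectivity 4 or 8.
#' @return logical H x W matrix `E` of boundary pixels.
#' @export
watershed_boundaries <- function(S, points, labeling = NULL, connectivity = 8) {
  S <- probability_map(S)
  points <- as_points(points)
  if (is.null(labeling)) labeling <- blob_labeling(S, points, connectivity)
  labels <- labeling$labels
  E <- matrix(FALSE, nrow(labels), ncol(labels))
  multi <- which(labeling$points_per_blob >= 2)
  for (b in multi) {
    inb <- labels == b
    # restrict to the blob's bounding box for speed
    rr <- range(which(rowSums(inb) > 0)); cc <- range(which(colSums(inb) > 0))
    sub <- inb[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    pts <- points[inb[points], , drop = FALSE]
    pts_sub <- cbind(pts[, 1] - rr[1] + 1L, pts[, 2] - cc[1] + 1L)
    elev_sub <- -S[rr[1]:rr[2], cc[1]:cc[2], 2, drop = TRUE]
    if (!is.matrix(elev_sub)) elev_sub <- matrix(elev_sub, nrow = rr[2] - rr[1] + 1)
    ws <- seeded_watershed(elev_sub, pts_sub, region = sub,
                           connectivity = connectivity)
    E[rr[1]:rr[2], cc[1]:cc[2]] <- E[rr[1]:rr[2], cc[1]:cc[2]] | ws$ridge
  }
  E
}
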