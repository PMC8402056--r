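# The localization-counting loss: four terms over a per-pixel softmax
# probability field S (channel 1 = background, channel 2 = ear) and the
# point annotations T. All logs are clamped at 1e-12.
#
#   L = L_image + L_point + L_split + L_fp
#
#   * image-level: the best pixel for every class present in the image must
#     be confident, and the best ear pixel must be suppressed when the
#     image holds no ear;
#   * point-level: every annotated pixel must be classified as ear;
#   * split: watershed ridge pixels inside blobs covering >= 2 points are
#     pushed to background, weighted by the blob's point count;
#   * false-positive: every pixel of a blob containing no point is pushed
#     to background.

#' Construct/validate a per-pixel class-probability map
#'
#' @param S numeric H x W x 2 array; channel 1 is background, channel 2 is
#'   ear. Each pixel's probabilities must be non-negative and sum to 1
#'   (tolerance 2e-6, which admits finite-difference probes).
#' @return `S` with class `probability_map`.
#' @export
probability_map <- function(S) {
  if (inherits(S, "probability_map")) return(S)
  if (!is.array(S) || length(dim(S)) != 3 || dim(S)[3] != 2)
    stopf("S must be an H x W x 2 array")
  if (any(S < -1e-9)) stopf("probabilities must be non-negative")
  tot <- S[, , 1] + S[, , 2]
  if (any(abs(tot - 1) > 2e-6))
    stopf("per-pixel probabilities must sum to 1 (max deviation %.2e)",
          max(abs(tot - 1)))
  class(S) <- c("probability_map", class(S))
  S
}

#' Image-level loss
#'
#' Over present classes C_e ({background} plus {ear} when any point exists)
#' the maximum probability must approach 1; over absent classes C_not_e
#' ({ear} when no point exists) the maximum probability must approach 0.
#'
#' @param S probability map.
#' @param points annotation points.
#' @return non-negative scalar.
#' @export
image_level_loss <- function(S, points) {
  S <- probability_map(S)
  points <- as_points(points)
  max_bg <- max(S[, , 1]); max_ear <- max(S[, , 2])
  if (nrow(points) > 0) {
    -(clog(max_bg) + clog(max_ear)) / 2
  } else {
    -clog(max_bg) - clog(1 - max_ear)
  }
}

#' Point-level loss
#'
#' Negative log ear-probability summed over the annotated pixels; all
#' unlabeled pixels are ignored.
#' @inheritParams image_level_loss
#' @export
point_level_loss <- function(S, points) {
  S <- probability_map(S)
  points <- as_points(points)
  if (nrow(points) == 0) return(0)
  check_points_in_bounds(points, dim(S)[1], dim(S)[2])
  ear <- S[, , 2]
  -sum(clog(ear[points]))
}

#' Split loss
#'
#' Watershed ridge pixels E inside multi-point blobs are pushed to the
#' background class, each weighted by the number of annotation points in
#' its blob (`variant = "lcfcn"`). `variant = "printed"` instead averages
#' the raw background probability over E, mirroring a published variant of
#' the formula whose prose contradicts it; it is provided for comparison
#' only.
#'
#' @param S probability map.
#' @param E logical boundary matrix from [watershed_boundaries()].
#' @param labeling [blob_labeling()] giving per-blob point tallies.
#' @param variant "lcfcn" (default) or "printed".
#' @export
split_loss <- function(S, E, labeling, variant = c("lcfcn", "printed")) {
  S <- probability_map(S)
  variant <- match.arg(variant)
  if (!any(E)) return(0)
  bg <- S[, , 1]
  if (variant == "printed") return(sum(bg[E]) / sum(E))
  alpha <- matrix(0, nrow(E), ncol(E))
  pos <- labeling$labels > 0
  alpha[pos] <- labeling$points_per_blob[labeling$labels[pos]]
  -sum(alpha[E] * clog(bg[E]))
}

#' False-positive loss
#'
#' Negative log background probability over every pixel of blobs that
#' contain no annotation point.
#' @param S probability map.
#' @param labeling [blob_labeling()].
#' @export
false_positive_loss <- function(S, labeling) {
  S <- probability_map(S)
  k <- length(labeling$points_per_blob)
  if (k == 0) return(0)
  fp_blobs <- which(labeling$points_per_blob == 0)
  if (length(fp_blobs) == 0) return(0)
  in_fp <- labeling$labels %in% fp_blobs & labeling$labels > 0
  -sum(clog(S[, , 1][in_fp]))
}

#' Localization-counting loss of a probability map
#'
#' Computes the four terms and their sum for one image.
#'
#' @param S probability map (H x W x 2).
#' @param points annotation points (one per ear).
#' @param connectivity blob/watershed connectivity, 4 or 8.
#' @param variant split-loss variant, see [split_loss()].
#' @param structure optional precomputed discrete structure (internal,
#'   lets the training loop share the blob labeling and watershed
#'   boundaries between the loss and its gradient).
#' @return object of class `loss_breakdown`: list with `image_level`,
#'   `point_level`, `split`, `false_positive`, `total`.
#' @export
lc_loss <- function(S, points, connectivity = 8, variant = "lcfcn",
                    structure = NULL) {
  S <- probability_map(S)
  points <- as_points(points)
  if (is.null(structure)) structure <- lc_structure(S, points, connectivity)
  labeling <- structure$labeling
  E <- structure$E
  li <- image_level_loss(S, points)
  lp <- point_level_loss(S, points)
  ls <- split_loss(S, E, labeling, variant)
  lf <- false_positive_loss(S, labeling)
  structure(list(image_level = li, point_level = lp, split = ls,
                 false_positive = lf, total = li + lp + ls + lf),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("LC loss: total %.4f (image %.4f + point %.4f + split %.4f + fp %.4f)\n",
              x$total, x$image_level, x$point_level, x$split, x$false_positive))
  invisible(x)
}

# Discrete structure shared by the loss and its gradients: the blob
# labeling of argmax(S) and the watershed boundary set E.
lc_structure <- function(S, points, connectivity = 8) {
  labeling <- blob_labeling(S, points, connectivity)
  E <- watershed_boundaries(S, points, labeling, connectivity)
  list(labeling = labeling, E = E)
}

# ---- analytic gradients -------------------------------------------------

# d(-log max(s, eps))/ds, zero below the clamp
dclog <- function(s) ifelse(s > .LOG_EPS, -1 / s, 0)

#' Gradient of the LC loss with respect to the probability map
#'
#' Treats the discrete structure (blob labeling, watershed boundaries,
#' argmax pixels of the image-level term) as fixed, which is the standard
#' subgradient used in training. Per-term gradients are available for
#' finite-difference checking.
#'
#' @inheritParams lc_loss
#' @param term one of "total", "image_level", "point_level", "split",
#'   "false_positive".
#' @return H x W x 2 array dL/dS.
#' @export
lc_loss_grad <- function(S, points, connectivity = 8, variant = "lcfcn",
                         term = "total", structure = NULL) {
  S <- probability_map(S)
  points <- as_points(points)
  if (is.null(structure)) structure <- lc_structure(S, points, connectivity)
  labeling <- structure$labeling
  E <- structure$E
  g <- array(0, dim(S))
  want <- function(t) term %in% c("total", t)

  if (want("image_level")) {
    bg <- S[, , 1]; ear <- S[, , 2]
    ibg <- arrayInd(which.max(bg), dim(bg))
    iear <- arrayInd(which.max(ear), dim(ear))
    if (nrow(points) > 0) {
      g[ibg[1], ibg[2], 1] <- g[ibg[1], ibg[2], 1] + dclog(bg[ibg]) / 2
      g[iear[1], iear[2], 2] <- g[iear[1], iear[2], 2] + dclog(ear[iear]) / 2
    } else {
      g[ibg[1], ibg[2], 1] <- g[ibg[1], ibg[2], 1] + dclog(bg[ibg])
      # -log(1 - max ear): d/dear = 1/(1 - ear) above the clamp
      me <- ear[iear]
      g[iear[1], iear[2], 2] <- g[iear[1], iear[2], 2] +
        if (1 - me > .LOG_EPS) 1 / (1 - me) else 0
    }
  }
  if (want("point_level") && nrow(points) > 0) {
    ear <- S[, , 2]
    for (i in seq_len(nrow(points)))
      g[points[i, 1], points[i, 2], 2] <- g[points[i, 1], points[i, 2], 2] +
        dclog(ear[points[i, 1], points[i, 2]])
  }
  if (want("split") && any(E)) {
    bg <- S[, , 1]
    alpha <- matrix(0, nrow(E), ncol(E))
    pos <- labeling$labels > 0
    alpha[pos] <- labeling$points_per_blob[labeling$labels[pos]]
    if (variant == "printed") {
      gb <- matrix(0, nrow(E), ncol(E)); gb[E] <- 1 / sum(E)
      g[, , 1] <- g[, , 1] + gb
    } else {
      gb <- matrix(0, nrow(E), ncol(E))
      gb[E] <- alpha[E] * dclog(bg[E])
      g[, , 1] <- g[, , 1] + gb
    }
  }
  if (want("false_positive")) {
    fp_blobs <- which(labeling$points_per_blob == 0)
    if (length(fp_blobs) > 0) {
      in_fp <- labeling$labels %in% fp_blobs & labeling$labels > 0
      bg <- S[, , 1]
      gb <- matrix(0, nrow(in_fp), ncol(in_fp))
      gb[in_fp] <- dclog(bg[in_fp])
      g[, , 1] <- g[, , 1] + gb
    }
  }
  g
}

# Gradient of the LC loss with respect to the logits Z (S = softmax(Z)),
# in the numerically exact cross-entropy form: every term is a weighted
# -log S_{i,c}, whose logit gradient at pixel i is weight * (S_i - e_c) --
# bounded even where S_{i,c} underflows, unlike chaining -1/S through the
# softmax. Equals softmax_backward(S, lc_loss_grad(S, ...)) wherever S is
# above the log clamp. Used by the training loop.
lc_loss_dZ <- function(S, points, connectivity = 8, variant = "lcfcn",
                       structure = NULL) {
  S <- probability_map(S)
  points <- as_points(points)
  if (is.null(structure)) structure <- lc_structure(S, points, connectivity)
  labeling <- structure$labeling; E <- structure$E
  dZ <- array(0, dim(S))
  add_ce <- function(dZ, r, c, cls, wt) {
    # weight * (S - e_cls) at pixel (r, c)
    dZ[r, c, 1] <- dZ[r, c, 1] + wt * (S[r, c, 1] - (cls == 1))
    dZ[r, c, 2] <- dZ[r, c, 2] + wt * (S[r, c, 2] - (cls == 2))
    dZ
  }
  # image-level
  ibg <- arrayInd(which.max(S[, , 1]), dim(S)[1:2])
  iear <- arrayInd(which.max(S[, , 2]), dim(S)[1:2])
  if (nrow(points) > 0) {
    dZ <- add_ce(dZ, ibg[1], ibg[2], 1, 0.5)
    dZ <- add_ce(dZ, iear[1], iear[2], 2, 0.5)
  } else {
    dZ <- add_ce(dZ, ibg[1], ibg[2], 1, 1)
    # -log(1 - max S_ear) == -log S_bg at that pixel for two classes
    dZ <- add_ce(dZ, iear[1], iear[2], 1, 1)
  }
  # point-level
  for (i in seq_len(nrow(points)))
    dZ <- add_ce(dZ, points[i, 1], points[i, 2], 2, 1)
  # split
  if (any(E)) {
    if (variant == "printed") {
      # d(mean S_bg over E)/dZ via the softmax jacobian
      G <- array(0, dim(S)); gb <- matrix(0, nrow(E), ncol(E)); gb[E] <- 1 / sum(E)
      G[, , 1] <- gb
      dZ <- dZ + softmax_backward(S, G)
    } else {
      alpha <- matrix(0, nrow(E), ncol(E))
      pos <- labeling$labels > 0
      alpha[pos] <- labeling$points_per_blob[labeling$labels[pos]]
      wE <- which(E)
      w1 <- alpha[wE]
      n <- prod(dim(S)[1:2])
      dZ1 <- dZ[, , 1]; dZ2 <- dZ[, , 2]
      dZ1[wE] <- dZ1[wE] + w1 * (S[, , 1][wE] - 1)
      dZ2[wE] <- dZ2[wE] + w1 * S[, , 2][wE]
      dZ[, , 1] <- dZ1; dZ[, , 2] <- dZ2
    }
  }
  # false-positive
  fp_blobs <- which(labeling$points_per_blob == 0)
  if (length(fp_blobs) > 0) {
    in_fp <- which(labeling$labels %in% fp_blobs & labeling$labels > 0)
    dZ1 <- dZ[, , 1]; dZ2 <- dZ[, , 2]
    dZ1[in_fp] <- dZ1[in_fp] + (S[, , 1][in_fp] - 1)
    dZ2[in_fp] <- dZ2[in_fp] + S[, , 2][in_fp]
    dZ[, , 1] <- dZ1; dZ[, , 2] <- dZ2
  }
  dZ
}

# Chain dL/dS through the per-pixel softmax: given S = softmax(Z) and
# G = dL/dS, returns dL/dZ with the same shape.
softmax_backward <- function(S, G) {
  inner <- S[, , 1] * G[, , 1] + S[, , 2] * G[, , 2]
  dZ <- array(0, dim(S))
  dZ[, , 1] <- S[, , 1] * (G[, , 1] - inner)
  dZ[, , 2] <- S[, , 2] * (G[, , 2] - inner)
  dZ
}
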