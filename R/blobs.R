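# Connected-component machinery. The counting method equates one blob of
# the predicted ear mask with one ear, so labeling must support both 4- and
# 8-connectivity (dense canopies merge more readily under 8, which is the
# default throughout).

neighbor_shifts <- function(connectivity) {
  if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else stopf("connectivity must be 4 or 8")
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Label connected foreground blobs of a binary mask
#'
#' Vectorized min-label propagation: each foreground pixel starts with a
#' unique id and repeatedly takes the minimum over its foreground
#' neighbourhood until a fixed point; labels are then renumbered 1..K in
#' first-pixel order (column-major scan).
#'
#' @param mask binary matrix (values 0/1 or logical).
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix, 0 = background, 1..K = blobs.
#' @export
label_blobs <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (is.logical(mask)) mask <- mask * 1
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary (0/1)")
  fg <- mask == 1
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[fg] <- seq_len(sum(fg))
  shifts <- neighbor_shifts(connectivity)
  repeat {
    new <- lab
    for (s in shifts) new <- pmin(new, shift_mat(lab, s[1], s[2]))
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, h, w)
  if (any(fg)) {
    ids <- sort(unique(lab[fg]))
    out[fg] <- match(lab[fg], ids)
  }
  out
}

#' Count connected foreground blobs
#'
#' @inheritParams label_blobs
#' @return list with `labels` (integer matrix) and `count`.
#' @export
count_blobs <- function(mask, connectivity = 8) {
  labels <- label_blobs(mask, connectivity)
  list(labels = labels, count = max(labels))
}

# Centroid (mean row, mean col) of each blob, K x 2.
blob_centroids <- function(labels) {
  k <- max(labels)
  if (k == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  cbind(row = as.numeric(tapply(idx[, 1], l, mean)),
        col = as.numeric(tapply(idx[, 2], l, mean)))
}

# Number of annotation points falling in each blob (named vector 1..K);
# points on background are excluded.
points_per_blob <- function(labels, points) {
  k <- max(labels)
  tally <- integer(k)
  if (k > 0 && nrow(points) > 0) {
    bl <- labels[points]
    bl <- bl[bl > 0]
    if (length(bl)) {
      tb <- table(bl)
      tally[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  tally
}

#' Blob labeling of a probability map with per-blob point tallies
#'
#' Blobs are connected components of the foreground of `argmax(S)` (ties at
#' probability exactly 0.5 go to background). Used by the split and
#' false-positive loss terms and by count prediction.
#'
#' @param S probability map (see [probability_map()]).
#' @param points annotation points.
#' @param connectivity 4 or 8.
#' @return object of class `blob_labeling`: list with `labels`,
#'   `points_per_blob`, `count`.
#' @export
blob_labeling <- function(S, points, connectivity = 8) {
  S <- probability_map(S)
  points <- as_points(points)
  mask <- (S[, , 2] > S[, , 1]) * 1
  labels <- label_blobs(mask, connectivity)
  structure(list(labels = labels,
                 points_per_blob = points_per_blob(labels, points),
                 count = max(labels)),
            class = "blob_labeling")
}
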