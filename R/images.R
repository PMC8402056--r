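# Raster convention: a numeric array H x W (x 3 for RGB) with values in
# [0, 1]; element [i, j] is the pixel in image row i (from the top) and
# column j (from the left). PNG files are read/written with the png package,
# whose arrays already use this orientation; JPEG goes through EBImage,
# whose (x, y) axis order is transposed at this boundary.

#' Read an RGB image
#'
#' @param path PNG or JPEG file.
#' @return numeric H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("no such image file: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    return(a)
  }
  e <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(e)) == 2) e <- array(rep(e, 3), c(dim(e), 3))
  aperm(e[, , 1:3, drop = FALSE], c(2, 1, 3))
}

#' Write an RGB image (PNG or JPEG, by file extension)
#'
#' @param pixels numeric H x W x 3 array in `[0, 1]`.
#' @param path output file.
#' @export
write_image <- function(pixels, path) {
  pixels <- clip01(pixels)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pixels, path)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(pixels, c(2, 1, 3)),
                                       colormode = "Color"), path)
  }
  invisible(path)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Bilinear resampling of a raster
#'
#' Works on a matrix or an H x W x C array. Sample positions follow the
#' half-pixel-center convention (output pixel p samples input coordinate
#' (p - 0.5) * H_in / H_out + 0.5), clamped at the borders.
#'
#' @param x matrix or 3-d array.
#' @param out_h,out_w output dimensions.
#' @return resampled raster of the same arity.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  R <- interp_matrix(d[1], out_h)
  C <- interp_matrix(d[2], out_w)
  if (length(d) == 2) return(R %*% x %*% t(C))
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- R %*% x[, , k] %*% t(C)
  out
}

# Dense 1-d linear interpolation operator (out_n x in_n), also used as the
# upsampling layer of the segmentation network (its transpose is the adjoint
# used in backprop).
interp_matrix <- function(in_n, out_n) {
  key <- sprintf("im_%d_%d", in_n, out_n)
  cached <- .earcount_cache[[key]]
  if (!is.null(cached)) return(cached)
  src <- (seq_len(out_n) - 0.5) * in_n / out_n + 0.5
  src <- pmin(pmax(src, 1), in_n)
  lo <- pmin(floor(src), in_n - 1L)
  if (in_n == 1) lo <- rep(1, out_n)
  hi <- pmin(lo + 1, in_n)
  w <- src - lo
  M <- matrix(0, out_n, in_n)
  M[cbind(seq_len(out_n), lo)] <- M[cbind(seq_len(out_n), lo)] + (1 - w)
  M[cbind(seq_len(out_n), hi)] <- M[cbind(seq_len(out_n), hi)] + w
  .earcount_cache[[key]] <- M
  M
}

.earcount_cache <- new.env(parent = emptyenv())
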