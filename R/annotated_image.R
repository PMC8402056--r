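#' Annotated field image
#'
#' The central data object: an RGB raster together with its point
#' annotations (one 1-based (row, col) pixel per ear) and the derived
#' ground-truth count. The count always equals the number of annotation
#' points; points are unique and in bounds.
#'
#' @param pixels numeric H x W x 3 array in `[0, 1]`.
#' @param points n x 2 matrix of (row, col) coordinates (or anything
#'   [as_points()] accepts). Duplicates are dropped with a warning.
#' @param image_id character scalar identifier.
#' @param meta optional list of generator metadata (ear masks, frame
#'   corners, ...), carried along untouched.
#' @return an object of class `annotated_image` with fields `pixels`,
#'   `points`, `image_id`, `count`, `meta`.
#' @export
annotated_image <- function(pixels, points = NULL, image_id = "img", meta = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stopf("pixels must be an H x W x 3 array")
  points <- as_points(points)
  check_points_in_bounds(points, dim(pixels)[1], dim(pixels)[2], "annotation point")
  points <- dedupe_points(points, context = "annotation points")
  structure(list(pixels = pixels, points = points, image_id = image_id,
                 count = nrow(points), meta = meta),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image '%s'> %d x %d px, %d ear point(s)\n",
              x$image_id, d[1], d[2], x$count))
  invisible(x)
}

#' @export
dim.annotated_image <- function(x) dim(x$pixels)

is_annotated_image <- function(x) inherits(x, "annotated_image")

#' Coerce a list of annotated images to an ear dataset
#'
#' A light container (class `ear_dataset`) over a list of
#' [annotated_image()] objects with unique ids.
#' @param images list of `annotated_image`.
#' @export
ear_dataset <- function(images) {
  if (is_annotated_image(images)) images <- list(images)
  stopifnot(all(vapply(images, is_annotated_image, TRUE)))
  ids <- vapply(images, function(a) a$image_id, "")
  if (anyDuplicated(ids)) stopf("duplicate image ids in dataset")
  names(images) <- ids
  structure(images, class = "ear_dataset")
}

#' @export
print.ear_dataset <- function(x, ...) {
  counts <- vapply(x, function(a) a$count, 0L)
  cat(sprintf("<ear_dataset> %d image(s), counts %d..%d (mean %.1f)\n",
              length(x), if (length(x)) min(counts) else 0L,
              if (length(x)) max(counts) else 0L, mean(counts)))
  invisible(x)
}

#' @export
`[.ear_dataset` <- function(x, i) ear_dataset(unclass(x)[i])

#' Ground-truth counts of a dataset as a data frame
#' @param dataset an `ear_dataset`.
#' @return data.frame with columns `image_id`, `count`.
#' @export
dataset_counts <- function(dataset) {
  data.frame(image_id = vapply(dataset, function(a) a$image_id, ""),
             count = vapply(dataset, function(a) a$count, 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}
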