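# Readers/writers for the point-annotation dataset layout:
#   images/<id>.png (or .jpg)   8-bit RGB rasters
#   masks/<id>.png              single-channel point masks (one nonzero
#                               pixel per ear, rest black)
#   counts.csv                  header image_id,count
# plus LabelMe JSON point files as an alternative annotation pathway.

#' Extract annotation points from a single-channel point mask
#'
#' Every nonzero pixel marks one ear. Points are returned in row-major
#' order (row, then column), 1-based.
#'
#' @param mask numeric or integer matrix (single channel).
#' @param image optional paired RGB image; if given, dimensions must match.
#' @return n x 2 integer matrix of (row, col).
#' @export
read_point_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask)) {
    if (is.array(mask) && length(dim(mask)) == 3 && dim(mask)[3] == 1)
      mask <- mask[, , 1]
    else stopf("mask must be a single-channel matrix")
  }
  if (!is.null(image)) {
    di <- if (is_annotated_image(image)) dim(image$pixels) else dim(image)
    if (di[1] != nrow(mask) || di[2] != ncol(mask))
      stopf("mask dimensions %d x %d do not match image %d x %d",
            nrow(mask), ncol(mask), di[1], di[2])
  }
  idx <- which(mask != 0, arr.ind = TRUE)
  # row-major order: sort by row then column
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  as_points(unname(idx))
}

#' Render annotation points as a single-channel point mask
#'
#' Inverse of [read_point_mask()]: a matrix of zeros with 1 at each point.
#'
#' @param points point matrix (see [as_points()]).
#' @param shape integer pair (H, W).
#' @export
write_point_mask <- function(points, shape) {
  points <- as_points(points)
  h <- shape[1]; w <- shape[2]
  check_points_in_bounds(points, h, w)
  m <- matrix(0, h, w)
  if (nrow(points)) m[points] <- 1
  m
}

#' Read a point-mask PNG file
#' @param path single-channel PNG file.
#' @inheritParams read_point_mask
#' @export
read_point_mask_png <- function(path, image = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  read_point_mask(a, image)
}

#' Write a point-mask PNG file
#' @inheritParams write_point_mask
#' @param path output PNG file.
#' @export
write_point_mask_png <- function(points, shape, path) {
  png::writePNG(write_point_mask(points, shape), path)
  invisible(path)
}

#' Parse point annotations from a LabelMe JSON document
#'
#' LabelMe stores shapes with (x, y) = (column, horizontal; row, vertical)
#' 0-based pixel coordinates; they are converted to this package's 1-based
#' (row, col) convention at this boundary. Non-point shapes are skipped
#' with a warning.
#'
#' @param json path to a LabelMe JSON file, or a JSON string.
#' @return n x 2 integer matrix of (row, col).
#' @export
read_labelme_points <- function(json) {
  doc <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e) stopf("malformed LabelMe document: %s",
                                            conditionMessage(e)))
  shapes <- doc$shapes
  if (is.null(shapes)) stopf("malformed LabelMe document: no 'shapes' field")
  pts <- list()
  skipped <- 0L
  for (s in shapes) {
    st <- s$shape_type
    if (is.null(st) || !identical(st, "point")) { skipped <- skipped + 1L; next }
    xy <- unlist(s$points[[1]])
    # (x, y) 0-based -> (row, col) 1-based
    pts[[length(pts) + 1L]] <- c(round(xy[2]) + 1L, round(xy[1]) + 1L)
  }
  if (skipped) warnf("%d non-point shape(s) skipped", skipped)
  as_points(pts)
}

#' Read / write per-image ground-truth counts
#'
#' CSV with header `image_id,count`.
#' @param path CSV file.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "count") %in% names(df)))
    stopf("counts CSV must have columns image_id,count")
  df$image_id <- as.character(df$image_id)
  df$count <- as.integer(df$count)
  df[c("image_id", "count")]
}

#' @rdname read_counts_csv
#' @param counts data.frame with columns `image_id`, `count`.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(all(c("image_id", "count") %in% names(counts)))
  utils::write.csv(counts[c("image_id", "count")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split image ids into training and test sets
#'
#' Random split by image id under a stored seed. For n ids and ratio
#' (a, b), the training set has round(n * a / (a + b)) ids.
#'
#' @param ids character vector of image ids (non-empty).
#' @param ratio positive integer pair, default `c(7, 3)`.
#' @param seed integer seed making the shuffle reproducible.
#' @return object of class `dataset_split`: list with `train_ids`,
#'   `test_ids`, `ratio`, `seed`.
#' @export
split_dataset <- function(ids, ratio = c(7, 3), seed = 1) {
  if (length(ids) == 0) stopf("cannot split an empty id set")
  if (length(ratio) != 2 || any(ratio <= 0)) stopf("ratio must be two positive numbers")
  if (anyDuplicated(ids)) stopf("duplicate ids")
  n_train <- round(length(ids) * ratio[1] / sum(ratio))
  perm <- with_seed(seed, sample(ids))
  structure(list(train_ids = perm[seq_len(n_train)],
                 test_ids = if (n_train < length(ids)) perm[(n_train + 1):length(ids)] else character(0),
                 ratio = ratio, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (ratio %g:%g, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio[1], x$ratio[2],
              as.integer(x$seed)))
  invisible(x)
}

#' Write an ear dataset to a directory
#'
#' Produces `images/<id>.png`, `masks/<id>.png` and `counts.csv`.
#' @param dataset an [ear_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dataset <- ear_dataset(dataset)
  ok <- dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "images")))
    stopf("cannot create output directory %s", dir)
  for (a in dataset) {
    write_image(a$pixels, file.path(dir, "images", paste0(a$image_id, ".png")))
    write_point_mask_png(a$points, dim(a$pixels)[1:2],
                         file.path(dir, "masks", paste0(a$image_id, ".png")))
  }
  write_counts_csv(dataset_counts(dataset), file.path(dir, "counts.csv"))
  invisible(dir)
}

#' Read an ear dataset from a directory written by [write_dataset()]
#' @param dir dataset directory.
#' @export
read_dataset <- function(dir) {
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.(png|jpe?g)$",
                     full.names = TRUE)
  if (length(imgs) == 0) stopf("no images under %s/images", dir)
  out <- lapply(imgs, function(f) {
    id <- sub("\\.[^.]+$", "", basename(f))
    px <- read_image(f)
    mf <- file.path(dir, "masks", paste0(id, ".png"))
    pts <- if (file.exists(mf)) read_point_mask_png(mf, px) else NULL
    annotated_image(px, pts, image_id = id)
  })
  ear_dataset(out)
}
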