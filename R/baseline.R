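# Classical (non-learned) ear counter: intensity thresholding plus
# morphology. Thin bright ears vanish under an erosion whose radius
# exceeds the ear half-width but not the leaf half-width; dilating back
# restores the broad leaves only, and XOR-ing with the denoised foreground
# leaves the ears. Area filters remove dirt/noise first and leaf residue
# last.

#' Configuration for the classical baseline counter
#'
#' @param binarize_method "otsu" (default) or "fixed".
#' @param fixed_threshold intensity threshold in `[0, 1]` when
#'   `binarize_method = "fixed"`.
#' @param min_noise_area components smaller than this (px) are removed
#'   from the binarized image before morphology.
#' @param erosion_radius,dilation_radius disk radii (px) of the
#'   erosion/dilation isolating the leaf image; the erosion radius must
#'   exceed the ear half-width and stay below the leaf half-width.
#' @param min_ear_area components smaller than this are removed from the
#'   final ear image.
#' @param connectivity 4 or 8 for all component steps.
#' @export
baseline_config <- function(binarize_method = c("otsu", "fixed"),
                            fixed_threshold = 0.5,
                            min_noise_area = 10,
                            erosion_radius = 4, dilation_radius = 4,
                            min_ear_area = 15, connectivity = 8) {
  binarize_method <- match.arg(binarize_method)
  if (erosion_radius < 1 || dilation_radius < 1) stopf("radii must be >= 1")
  if (min_noise_area < 0 || min_ear_area < 0) stopf("areas must be >= 0")
  structure(list(binarize_method = binarize_method,
                 fixed_threshold = fixed_threshold,
                 min_noise_area = min_noise_area,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 min_ear_area = min_ear_area,
                 connectivity = connectivity),
            class = "baseline_config")
}

#' Intensity component of an RGB image
#'
#' The I component of the HSI decomposition: (R + G + B) / 3, in `[0, 1]`.
#' @param pixels H x W x 3 array or [annotated_image()].
#' @export
rgb_to_intensity <- function(pixels) {
  if (is_annotated_image(pixels)) pixels <- pixels$pixels
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stopf("rgb_to_intensity needs an H x W x 3 RGB array")
  I <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  if (is.null(dim(I))) I <- matrix(I, dim(pixels)[1], dim(pixels)[2])
  I
}

# drop components with area < min_area
area_filter <- function(mask, min_area, connectivity) {
  if (min_area <= 0 || !any(mask == 1)) return(mask)
  lab <- label_blobs(mask, connectivity)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  (lab %in% keep & lab > 0) * 1
}

disk_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, shape = "disc")

#' Classical seven-step baseline count
#'
#' 1. RGB -> HSI intensity; 2. binarize (Otsu or fixed threshold);
#' 3. two-pass connected-domain denoising (small-component removal);
#' 4. erosion-then-dilation to suppress thin ears, yielding the leaf
#' image; 5. XOR of the denoised mask with the leaf image; 6. remove
#' residual small components; 7. count the surviving components.
#'
#' @param image [annotated_image()] or H x W x 3 array.
#' @param config a [baseline_config()].
#' @return object of class `baseline_count`: list with `count` and all
#'   intermediate masks (`intensity`, `binary`, `denoised`, `leaf`,
#'   `xor`, `ears`).
#' @export
baseline_count <- function(image, config = baseline_config()) {
  px <- if (is_annotated_image(image)) image$pixels else image
  if (!is.array(px) || length(dim(px)) != 3 || dim(px)[3] != 3)
    stopf("baseline_count needs an RGB image")
  I <- rgb_to_intensity(px)
  thr <- if (config$binarize_method == "otsu")
    EBImage::otsu(EBImage::Image(I)) else config$fixed_threshold
  binary <- (I > thr) * 1
  denoised <- area_filter(binary, config$min_noise_area, config$connectivity)
  eroded <- EBImage::imageData(EBImage::erode(denoised, disk_brush(config$erosion_radius)))
  leaf <- EBImage::imageData(EBImage::dilate(eroded, disk_brush(config$dilation_radius)))
  leaf <- (leaf > 0) * 1
  xor_mask <- ((denoised + leaf) == 1) * 1
  ears <- area_filter(xor_mask, config$min_ear_area, config$connectivity)
  cb <- count_blobs(ears, config$connectivity)
  structure(list(count = cb$count, labels = cb$labels,
                 intensity = I, binary = binary, denoised = denoised,
                 leaf = leaf, xor = xor_mask, ears = ears,
                 threshold = as.numeric(thr), config = config),
            class = "baseline_count")
}

#' @export
print.baseline_count <- function(x, ...) {
  cat(sprintf("<baseline_count> %d ear(s) (threshold %.3f)\n", x$count, x$threshold))
  invisible(x)
}

#' Run the classical baseline over a dataset
#'
#' @param dataset an [ear_dataset()].
#' @param config a [baseline_config()].
#' @return data.frame `image_id, count`.
#' @export
baseline_count_dataset <- function(dataset, config = baseline_config()) {
  dataset <- ear_dataset(dataset)
  data.frame(image_id = vapply(dataset, function(a) a$image_id, ""),
             count = vapply(dataset, function(a) baseline_count(a, config)$count, 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}
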