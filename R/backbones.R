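# Backbone constructors. Every backbone maps H x W x 3 -> H x W x 2 logits
# (softmax applied downstream), for any H, W divisible by its stride.
#
#   tiny         4-conv encoder-decoder, stride 2, < 100k parameters; the
#                desk-scale backbone every test trains.
#   vgg16-fcn    the 13 VGG-16 convolution layers, 1x1 classifier at
#                stride 32, bilinear upsample x32 (FCN-32s layout).
#   resnet50-fcn conv7x7/2 + pool + the (3,4,6,3) bottleneck stages of
#                ResNet-50 with batch-size-1 batch norm, 1x1 classifier,
#                bilinear upsample x32. The stem pool is 2x2/stride 2.

#' Build a segmentation model
#'
#' @param backbone "tiny", "vgg16-fcn" or "resnet50-fcn".
#' @param seed integer seed for the (He) weight initialisation.
#' @return object of class `ear_segmenter`: list with `layers`, `backbone`,
#'   `stride`, `seed`, `n_params`.
#' @export
build_model <- function(backbone = "tiny", seed = 1) {
  layers <- switch(backbone,
    "tiny" = list(
      nn_conv(3, 16, 3), nn_relu(),
      nn_conv(16, 16, 3), nn_relu(),
      nn_maxpool(),
      nn_conv(16, 32, 3), nn_relu(),
      nn_upsample(2),
      nn_conv(32, 2, 1)),
    "vgg16-fcn" = {
      cfg <- list(c(3, 64), c(64, 64), "M", c(64, 128), c(128, 128), "M",
                  c(128, 256), c(256, 256), c(256, 256), "M",
                  c(256, 512), c(512, 512), c(512, 512), "M",
                  c(512, 512), c(512, 512), c(512, 512), "M")
      ls <- list()
      for (e in cfg) {
        if (identical(e, "M")) ls[[length(ls) + 1]] <- nn_maxpool()
        else { ls[[length(ls) + 1]] <- nn_conv(e[1], e[2], 3)
               ls[[length(ls) + 1]] <- nn_relu() }
      }
      c(ls, list(nn_conv(512, 2, 1), nn_upsample(32)))
    },
    "resnet50-fcn" = {
      bottleneck <- function(in_ch, mid, out_ch, stride = 1) {
        proj <- if (stride != 1 || in_ch != out_ch)
          nn_conv(in_ch, out_ch, 1, stride = stride, pad = 0) else NULL
        nn_block(list(
          nn_conv(in_ch, mid, 1, stride = stride, pad = 0), nn_bn(mid), nn_relu(),
          nn_conv(mid, mid, 3), nn_bn(mid), nn_relu(),
          nn_conv(mid, out_ch, 1, pad = 0), nn_bn(out_ch)), projection = proj)
      }
      stage <- function(in_ch, mid, out_ch, n, stride) {
        ls <- list(bottleneck(in_ch, mid, out_ch, stride))
        for (i in seq_len(n - 1)) ls[[i + 1]] <- bottleneck(out_ch, mid, out_ch)
        ls
      }
      c(list(nn_conv(3, 64, 7, stride = 2, pad = 3), nn_bn(64), nn_relu(),
             nn_maxpool()),
        stage(64, 64, 256, 3, 1),
        stage(256, 128, 512, 4, 2),
        stage(512, 256, 1024, 6, 2),
        stage(1024, 512, 2048, 3, 2),
        list(nn_conv(2048, 2, 1), nn_upsample(32)))
    },
    stopf("unknown backbone '%s' (use tiny, vgg16-fcn or resnet50-fcn)", backbone))
  layers <- with_seed(seed, init_params(layers))
  # Background-prior head initialisation: the classifier bias starts at
  # (+2, -2), so the untrained model predicts background everywhere. The
  # split and false-positive loss terms are then zero at the start of
  # training and ear blobs grow outward from the annotated pixels, instead
  # of the whole image starting as one giant blob whose split/FP gradients
  # swamp the handful of point-level ones.
  for (i in seq_along(layers))
    if (identical(layers[[i]]$type, "conv") && layers[[i]]$out_ch == 2) {
      layers[[i]]$b <- c(2, -2)
      layers[[i]]$W <- layers[[i]]$W * 0.01   # head small enough for the
    }                                          # bias prior to dominate
  n_params <- sum(lengths(collect_params(layers)))
  structure(list(layers = layers, backbone = backbone,
                 stride = switch(backbone, tiny = 2L, 32L),
                 seed = seed, n_params = n_params),
            class = "ear_segmenter")
}

#' @export
print.ear_segmenter <- function(x, ...) {
  cat(sprintf("<ear_segmenter> backbone %s, %s parameters, stride %d\n",
              x$backbone, format(x$n_params, big.mark = ","), x$stride))
  invisible(x)
}

#' Per-pixel class probabilities for one image
#'
#' @param model an `ear_segmenter`.
#' @param pixels H x W x 3 array (H, W divisible by the model stride) or an
#'   [annotated_image()].
#' @param normalize per-channel (mean, sd) normalisation list, as stored on
#'   a fitted model; NULL for raw input.
#' @return a [probability_map()].
#' @export
predict_probabilities <- function(model, pixels, normalize = NULL) {
  if (is_annotated_image(pixels)) pixels <- pixels$pixels
  d <- dim(pixels)
  if (any(d[1:2] %% model$stride != 0))
    stopf("input %d x %d not divisible by backbone stride %d",
          d[1], d[2], model$stride)
  if (!is.null(normalize))
    for (k in 1:3) pixels[, , k] <- (pixels[, , k] - normalize$mean[k]) / normalize$sd[k]
  softmax2(model_forward(model, pixels)$logits)
}
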