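#' Fit a point-supervised ear-counting model
#'
#' Trains a fully convolutional segmentation network under the
#' localization-counting loss: only one annotated pixel per ear is needed,
#' and at inference the count is the number of connected foreground blobs
#' of the predicted mask. Training is plain stochastic gradient descent
#' with momentum and weight decay over single images (batch size 1), the
#' regime the stated hyperparameters presuppose.
#'
#' @param data an [ear_dataset()] (or list of [annotated_image()]) with
#'   point annotations.
#' @param backbone "tiny" (default), "vgg16-fcn" or "resnet50-fcn".
#' @param epochs number of passes over the data (default 180).
#' @param learning_rate fixed SGD step size (default 1e-5, the
#'   fine-tuning regime for a pretrained backbone; train the `tiny`
#'   backbone from scratch at about 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty coefficient (default 5e-4).
#' @param connectivity blob/watershed connectivity, 8 (default) or 4.
#' @param max_grad_norm per-image clip on the Euclidean norm of the
#'   logit gradient (default 25). The split and false-positive terms are
#'   unnormalised sums over pixels, so a single image whose blobs merge
#'   across several annotated points can emit a gradient orders of
#'   magnitude above the point-level terms; clipping preserves its
#'   direction while keeping SGD-with-momentum stable. `Inf` disables.
#' @param seed integer seed governing weight init and epoch shuffling.
#' @param pretrained optional path to a serialized model (RDS) whose
#'   weights initialise the backbone (transfer learning hook); never
#'   required.
#' @param variant split-loss variant, see [split_loss()].
#' @param verbose print per-epoch mean losses.
#' @return an object of class `lcfcn`: the trained model plus the training
#'   log (`$log`, one row per epoch with columns
#'   `epoch, image_level, point_level, split, false_positive, total`),
#'   the input normalisation statistics, fitted training counts and the
#'   full configuration. Methods: `print`, `summary`, `predict`, `plot`,
#'   `coef`, `fitted`, `residuals`.
#' @seealso [predict_count()], [evaluate_counts()]
#' @export
lcfcn <- function(data, backbone = "tiny", epochs = 180,
                  learning_rate = 1e-5, momentum = 0.9, weight_decay = 5e-4,
                  connectivity = 8, max_grad_norm = 25, seed = 1,
                  pretrained = NULL, variant = "lcfcn", verbose = FALSE) {
  data <- ear_dataset(data)
  if (length(data) == 0) stopf("empty training set")
  if (epochs < 0 || epochs != round(epochs)) stopf("epochs must be a non-negative integer")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  for (a in data)
    if (a$count > prod(dim(a$pixels)[1:2]))
      stopf("image %s has more points than pixels", a$image_id)

  model <- if (!is.null(pretrained)) readRDS(pretrained)$model
           else build_model(backbone, seed = seed)

  # per-channel normalisation over the training set
  ch_mean <- numeric(3); ch_sq <- numeric(3); npx <- 0
  for (a in data) {
    for (k in 1:3) { ch_mean[k] <- ch_mean[k] + sum(a$pixels[, , k])
                     ch_sq[k] <- ch_sq[k] + sum(a$pixels[, , k]^2) }
    npx <- npx + prod(dim(a$pixels)[1:2])
  }
  ch_mean <- ch_mean / npx
  ch_sd <- pmax(sqrt(ch_sq / npx - ch_mean^2), 1e-6)
  normalize <- list(mean = ch_mean, sd = ch_sd)

  norm_px <- lapply(data, function(a) {
    x <- a$pixels
    for (k in 1:3) x[, , k] <- (x[, , k] - ch_mean[k]) / ch_sd[k]
    x
  })

  velocity <- vector("list", length(model$layers))
  log <- data.frame(epoch = integer(0), image_level = numeric(0),
                    point_level = numeric(0), split = numeric(0),
                    false_positive = numeric(0), total = numeric(0))
  epoch_orders <- with_seed(seed + 1,
    lapply(seq_len(max(epochs, 1)), function(e) sample(length(data))))

  if (epochs > 0) for (e in seq_len(epochs)) {
    terms <- c(image_level = 0, point_level = 0, split = 0,
               false_positive = 0, total = 0)
    for (i in epoch_orders[[e]]) {
      a <- data[[i]]
      fw <- model_forward(model, norm_px[[i]], keep_caches = TRUE)
      S <- softmax2(fw$logits)
      str <- lc_structure(S, a$points, connectivity)
      lb <- lc_loss(S, a$points, connectivity, variant, structure = str)
      dZ <- lc_loss_dZ(S, a$points, connectivity, variant, structure = str)
      gn <- sqrt(sum(dZ^2))
      if (is.finite(max_grad_norm) && gn > max_grad_norm)
        dZ <- dZ * (max_grad_norm / gn)
      grads <- model_backward(model, fw$caches, dZ)
      upd <- sgd_update(model$layers, grads, velocity,
                        learning_rate, momentum, weight_decay)
      model$layers <- upd$layers
      velocity <- upd$velocity
      terms <- terms + unlist(lb)[names(terms)]
    }
    log[e, ] <- c(e, terms / length(data))
    if (verbose)
      message(sprintf("epoch %3d  total %.4f", e, terms["total"] / length(data)))
  }

  fit <- structure(list(
    model = model, normalize = normalize, log = log,
    config = list(backbone = backbone, epochs = epochs, batch_size = 1,
                  learning_rate = learning_rate, momentum = momentum,
                  weight_decay = weight_decay, connectivity = connectivity,
                  max_grad_norm = max_grad_norm,
                  seed = seed, variant = variant,
                  pretrained = pretrained),
    n_train = length(data)), class = "lcfcn")

  tr <- dataset_counts(data)
  tr$fitted <- vapply(data, function(a) predict_count(fit, a)$blob_count, 0L)
  fit$train_counts <- tr
  fit
}

#' Predicted count for one image
#'
#' The inference chain: per-pixel class probabilities, argmax binary mask
#' (ties at exactly 0.5 go to background), connected-component labeling,
#' count = number of blobs.
#'
#' @param object a fitted [lcfcn()] model (or a bare `ear_segmenter`).
#' @param image an [annotated_image()] or H x W x 3 array.
#' @param connectivity override the fit's connectivity.
#' @return object of class `count_prediction`: list with `image_id`,
#'   `binary_mask`, `blob_count`, `blob_centroids`, `prob`.
#' @export
predict_count <- function(object, image, connectivity = NULL) {
  if (inherits(object, "lcfcn")) {
    model <- object$model
    normalize <- object$normalize
    if (is.null(connectivity)) connectivity <- object$config$connectivity
  } else {
    model <- object; normalize <- NULL
    if (is.null(connectivity)) connectivity <- 8
  }
  id <- if (is_annotated_image(image)) image$image_id else "img"
  S <- predict_probabilities(model, image, normalize)
  mask <- (S[, , 2] > S[, , 1]) * 1
  cb <- count_blobs(mask, connectivity)
  structure(list(image_id = id, binary_mask = mask,
                 blob_count = cb$count,
                 blob_centroids = blob_centroids(cb$labels),
                 prob = S),
            class = "count_prediction")
}

#' @export
print.count_prediction <- function(x, ...) {
  cat(sprintf("<count_prediction '%s'> %d blob(s)\n", x$image_id, x$blob_count))
  invisible(x)
}

#' @export
print.lcfcn <- function(x, ...) {
  cat(sprintf("Point-supervised ear counting model (LC-FCN)\n"))
  cat(sprintf("  backbone: %s (%s parameters)\n", x$model$backbone,
              format(x$model$n_params, big.mark = ",")))
  cat(sprintf("  trained:  %d epoch(s) on %d image(s), lr %g, momentum %g, weight decay %g\n",
              x$config$epochs, x$n_train, x$config$learning_rate,
              x$config$momentum, x$config$weight_decay))
  if (nrow(x$log))
    cat(sprintf("  final mean LC loss: %.4f\n", x$log$total[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.lcfcn <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(config = object$config, n_train = object$n_train,
              log = object$log,
              train_mae = mean(abs(res)),
              first_total = if (nrow(object$log)) object$log$total[1] else NA_real_,
              final_total = if (nrow(object$log)) object$log$total[nrow(object$log)] else NA_real_)
  class(out) <- "summary.lcfcn"
  out
}

#' @export
print.summary.lcfcn <- function(x, ...) {
  cat(sprintf("LC-FCN fit: %s backbone, %d training image(s), %d epoch(s)\n",
              x$config$backbone, x$n_train, x$config$epochs))
  if (!is.na(x$first_total))
    cat(sprintf("  mean LC loss %.4f -> %.4f\n", x$first_total, x$final_total))
  cat(sprintf("  training-count MAE: %.3f\n", x$train_mae))
  invisible(x)
}

#' @export
predict.lcfcn <- function(object, newdata, type = c("count", "prediction", "prob"), ...) {
  type <- match.arg(type)
  single <- is_annotated_image(newdata) ||
    (is.array(newdata) && length(dim(newdata)) == 3)
  items <- if (single) list(newdata) else newdata
  preds <- lapply(items, function(im) predict_count(object, im))
  if (type == "prob") {
    out <- lapply(preds, `[[`, "prob")
    return(if (single) out[[1]] else out)
  }
  if (type == "prediction") return(if (single) preds[[1]] else preds)
  data.frame(image_id = vapply(preds, `[[`, "", "image_id"),
             count = vapply(preds, `[[`, 0L, "blob_count"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
fitted.lcfcn <- function(object, ...) object$train_counts$fitted

#' @export
residuals.lcfcn <- function(object, ...)
  object$train_counts$fitted - object$train_counts$count

#' @export
coef.lcfcn <- function(object, ...) {
  p <- collect_params(object$model$layers)
  unlist(p)
}

#' Training-loss curves of a fitted LC-FCN model
#'
#' @param x a fitted [lcfcn()].
#' @param which "total" or "terms" (the four components).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lcfcn <- function(x, which = c("total", "terms"), ...) {
  which <- match.arg(which)
  if (!nrow(x$log)) { warnf("no epochs trained; nothing to plot"); return(invisible(x)) }
  if (which == "total") {
    graphics::plot(x$log$epoch, x$log$total, type = "l", xlab = "epoch",
                   ylab = "mean LC loss", main = "Training loss", ...)
  } else {
    graphics::matplot(x$log$epoch,
                      as.matrix(x$log[c("image_level", "point_level",
                                        "split", "false_positive")]),
                      type = "l", lty = 1, xlab = "epoch", ylab = "mean loss",
                      main = "LC loss terms", ...)
    graphics::legend("topright", c("image", "point", "split", "false positive"),
                     col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Serialize / restore a fitted model
#'
#' The RDS carries the weights together with the full configuration and
#' seed, so a run can be reproduced from the file alone.
#' @param fit a fitted [lcfcn()].
#' @param path output RDS path.
#' @export
save_lcfcn <- function(fit, path) { saveRDS(fit, path); invisible(path) }

#' @rdname save_lcfcn
#' @export
load_lcfcn <- function(path) readRDS(path)
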