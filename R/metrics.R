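# Count-evaluation metrics: MAE, RMSE, range-normalized RMSE (percent) and
# the mean accuracy rate 100 * mean(1 - |h - y| / y).

#' Evaluate predicted against true counts
#'
#' @param predictions numeric vector of predicted counts h, or a
#'   data.frame with `image_id, count` (joined to `truths` by id).
#' @param truths numeric vector of true counts y (non-negative), or a
#'   matching data.frame.
#' @param image_ids optional ids for the per-image table.
#' @return object of class `eval_report`: list with `mae`, `rmse`,
#'   `nrmse_percent` (NA with a warning when the truth range is zero),
#'   `acc_rate_percent` (images with y = 0 are excluded and counted in
#'   `n_zero_truth`), `n_images`, and a `per_image` data.frame with
#'   columns `image_id, h, y, abs_err`.
#' @export
evaluate_counts <- function(predictions, truths, image_ids = NULL) {
  if (is.data.frame(predictions) && is.data.frame(truths)) {
    m <- merge(predictions, truths, by = "image_id", suffixes = c("_pred", "_true"))
    if (nrow(m) != nrow(predictions) || nrow(m) != nrow(truths))
      stopf("prediction and truth ids do not match")
    image_ids <- m$image_id
    predictions <- m$count_pred; truths <- m$count_true
  }
  h <- as.numeric(predictions); y <- as.numeric(truths)
  if (length(h) != length(y)) stopf("prediction/truth length mismatch (%d vs %d)",
                                    length(h), length(y))
  if (length(h) == 0) stopf("empty input")
  if (any(y < 0)) stopf("true counts must be non-negative")
  if (is.null(image_ids)) image_ids <- as.character(seq_along(h))

  err <- h - y
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  rng <- max(y) - min(y)
  nrmse <- if (rng > 0) 100 * rmse / rng else {
    warnf("all true counts identical: nRMSE undefined (NA)")
    NA_real_
  }
  nz <- y > 0
  acc <- if (any(nz)) 100 * mean(1 - abs(err[nz]) / y[nz]) else NA_real_

  structure(list(mae = mae, rmse = rmse, nrmse_percent = nrmse,
                 acc_rate_percent = acc, n_images = length(h),
                 n_zero_truth = sum(!nz),
                 per_image = data.frame(image_id = image_ids, h = h, y = y,
                                        abs_err = abs(err),
                                        stringsAsFactors = FALSE)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Count evaluation over %d image(s)\n", x$n_images))
  cat(sprintf("  MAE   %.3f\n  RMSE  %.3f\n", x$mae, x$rmse))
  cat(sprintf("  nRMSE %s\n", if (is.na(x$nrmse_percent)) "undefined (zero range)"
              else sprintf("%.2f%%", x$nrmse_percent)))
  cat(sprintf("  Acc   %s\n", if (is.na(x$acc_rate_percent)) "undefined"
              else sprintf("%.2f%%", x$acc_rate_percent)))
  if (x$n_zero_truth > 0)
    cat(sprintf("  (%d image(s) with true count 0 excluded from Acc)\n", x$n_zero_truth))
  invisible(x)
}

#' Predicted-versus-true scatter of an evaluation report
#' @param x an `eval_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eval_report <- function(x, ...) {
  graphics::plot(x$per_image$y, x$per_image$h, xlab = "true count",
                 ylab = "predicted count", main = "Predicted vs true", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
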