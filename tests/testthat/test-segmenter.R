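# Blob counting, backbone contracts, the training loop, and the
# inference chain from probabilities to a count.

test_that("count_blobs matches the flood-fill oracle on every 3x3 mask", {
  for (m in all_3x3_masks()) {
    for (conn in c(4, 8)) {
      got <- count_blobs(m, conn)
      want <- flood_fill_labels(m, conn)
      expect_equal(got$count, max(want))
      # identical partitions up to label names
      if (got$count > 0) {
        key <- paste(got$labels[m == 1], want[m == 1])
        expect_equal(length(unique(key)), got$count)
      }
    }
  }
})

test_that("count_blobs matches the oracle on random 16x16 masks", {
  set.seed(19)
  for (rep in 1:100) {
    m <- matrix(rbinom(256, 1, runif(1, 0.2, 0.7)), 16, 16)
    conn <- sample(c(4, 8), 1)
    expect_equal(count_blobs(m, conn)$count, max(flood_fill_labels(m, conn)))
  }
})

test_that("connectivity semantics and input validation", {
  m <- matrix(0, 5, 5); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(count_blobs(m, 8)$count, 1)
  expect_equal(count_blobs(m, 4)$count, 2)
  expect_equal(count_blobs(matrix(0, 4, 4))$count, 0)
  expect_error(count_blobs(matrix(2, 3, 3)), "binary")
  expect_error(count_blobs(matrix(0.5, 3, 3)), "binary")
  # labels are canonical (first-pixel order), so independent of input history
  expect_equal(label_blobs(m, 4), flood_fill_labels(m, 4))
})

test_that("4-connected labeling agrees with EBImage::bwlabel", {
  set.seed(3)
  for (rep in 1:10) {
    m <- matrix(rbinom(400, 1, 0.4), 20, 20)
    expect_equal(count_blobs(m, 4)$count, max(EBImage::bwlabel(m)))
  }
})

test_that("backbones produce per-pixel two-class probabilities", {
  mod <- build_model("tiny", seed = 1)
  expect_lt(mod$n_params, 1e5)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  S <- predict_probabilities(mod, x)
  expect_equal(dim(S), c(64, 64, 2))
  expect_lt(max(abs(S[, , 1] + S[, , 2] - 1)), 1e-9)

  # same seed, identical initial parameters; different seed differs
  expect_identical(coef_vec <- unlist(earcount:::collect_params(mod$layers)),
                   unlist(earcount:::collect_params(build_model("tiny", seed = 1)$layers)))
  expect_false(identical(coef_vec,
                         unlist(earcount:::collect_params(build_model("tiny", seed = 2)$layers))))

  expect_error(build_model("mobilenet"), "unknown backbone")
  expect_error(predict_probabilities(mod, array(0, c(63, 64, 3))), "divisible")
})

test_that("the deep backbones keep the full-resolution output contract", {
  v <- build_model("vgg16-fcn", seed = 1)
  Sv <- predict_probabilities(v, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(Sv), c(64, 64, 2))
  expect_lt(max(abs(Sv[, , 1] + Sv[, , 2] - 1)), 1e-9)

  r <- build_model("resnet50-fcn", seed = 1)
  expect_gt(r$n_params, 1e6)
  Sr <- predict_probabilities(r, array(runif(96 * 96 * 3), c(96, 96, 3)))
  expect_equal(dim(Sr), c(96, 96, 2))
  expect_lt(max(abs(Sr[, , 1] + Sr[, , 2] - 1)), 1e-9)
})

test_that("network gradients match finite differences through every layer type", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  mod <- build_model("tiny", seed = 5)
  R <- array(rnorm(8 * 8 * 2), c(8, 8, 2))   # random linear functional
  env <- asNamespace("earcount")
  fw <- env$model_forward(mod, x, keep_caches = TRUE)
  grads <- env$model_backward(mod, fw$caches, R)
  h <- 1e-5
  conv_layers <- which(vapply(mod$layers, function(l) l$type == "conv", TRUE))
  for (li in conv_layers) {
    for (probe in 1:3) {
      i <- sample(length(mod$layers[[li]]$W), 1)
      m2 <- mod; m2$layers[[li]]$W[i] <- m2$layers[[li]]$W[i] + h
      m3 <- mod; m3$layers[[li]]$W[i] <- m3$layers[[li]]$W[i] - h
      fd <- (sum(R * env$model_forward(m2, x)$logits) -
             sum(R * env$model_forward(m3, x)$logits)) / (2 * h)
      expect_lt(abs(fd - grads[[li]]$W[i]), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("an untrained (background-prior) model predicts zero blobs", {
  mod <- build_model("tiny", seed = 2)
  img <- simulate_image(field_sim_config(image_size = c(32, 32),
                                         count_law = list("fixed", 3), seed = 6))
  pred <- predict_count(mod, img)
  expect_equal(pred$blob_count, 0)
  expect_equal(nrow(pred$blob_centroids), 0)
})

test_that("predict_count counts disjoint mask regions with centroids inside", {
  m <- matrix(0, 8, 8); m[2:3, 2:3] <- 1; m[6:7, 6:7] <- 1
  cb <- count_blobs(m)
  expect_equal(cb$count, 2)
  cent <- earcount:::blob_centroids(cb$labels)
  expect_equal(unname(cent), rbind(c(2.5, 2.5), c(6.5, 6.5)))
})

test_that("training is deterministic, resumable from zero epochs, and converges", {
  cfg <- field_sim_config(image_size = c(64, 64), count_law = list("uniform", 3, 12),
                          overlap_fraction = 0, seed = 7)
  ds <- simulate_dataset(cfg, 20)

  f0 <- lcfcn(ds, backbone = "tiny", epochs = 0, seed = 3)
  expect_equal(nrow(f0$log), 0)
  expect_identical(coef(f0), coef(structure(list(model = build_model("tiny", seed = 3)),
                                            class = "lcfcn")))

  fa <- lcfcn(ds[1:4], backbone = "tiny", epochs = 2, learning_rate = 3e-4, seed = 9)
  fb <- lcfcn(ds[1:4], backbone = "tiny", epochs = 2, learning_rate = 3e-4, seed = 9)
  expect_identical(fa$log, fb$log)
  expect_identical(coef(fa), coef(fb))

  # convergence on easy synthetic data: mean total loss falls by >= 50%
  fit <- lcfcn(ds, backbone = "tiny", epochs = 50, learning_rate = 1e-4, seed = 1)
  expect_lt(fit$log$total[50], 0.5 * fit$log$total[1])
  expect_named(fit$log, c("epoch", "image_level", "point_level", "split",
                          "false_positive", "total"))
  # model methods are coherent
  expect_equal(length(coef(fit)), fit$model$n_params)
  expect_equal(fitted(fit) - dataset_counts(ds)$count, residuals(fit))
  expect_output(print(fit), "backbone: tiny")
  expect_output(print(summary(fit)), "training-count MAE")
  assign("fit50_cache", fit, envir = .earcount_test_cache)
  assign("ds20_cache", ds, envir = .earcount_test_cache)
})

test_that("a trained model has learned the training images", {
  fit <- get("fit50_cache", envir = .earcount_test_cache)
  ds <- get("ds20_cache", envir = .earcount_test_cache)
  rep <- evaluate_counts(predict(fit, ds), dataset_counts(ds))
  expect_lt(rep$mae, 1)
})

test_that("data errors are caught before training", {
  px <- array(0.5, c(2, 16, 3))   # fewer pixels than claimed points is impossible
  expect_error(lcfcn(list(), epochs = 1), "empty")
  a <- annotated_image(array(0.5, c(32, 32, 3)), rbind(c(1, 1)), "t")
  expect_error(lcfcn(ear_dataset(a), epochs = 1, learning_rate = -1), "positive")
})

test_that("serialization preserves the model and its configuration", {
  fit <- get("fit50_cache", envir = .earcount_test_cache)
  f <- tempfile(fileext = ".rds")
  save_lcfcn(fit, f)
  back <- load_lcfcn(f)
  expect_identical(coef(back), coef(fit))
  expect_identical(back$config, fit$config)
})
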