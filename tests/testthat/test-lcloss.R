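# The four localization-counting loss terms: hand-derived values on small
# fixtures, loop oracles, the perfect-prediction limit, and agreement of
# analytic gradients with finite differences.

test_that("probability maps are validated", {
  S <- array(0.5, c(3, 3, 2))
  expect_s3_class(probability_map(S), "probability_map")
  bad <- S; bad[1, 1, 1] <- 0.2
  expect_error(probability_map(bad), "sum to 1")
  expect_error(probability_map(array(0.5, c(3, 3, 3))), "H x W x 2")
  neg <- S; neg[1, 1, ] <- c(1.2, -0.2)
  expect_error(probability_map(neg), "non-negative")
})

test_that("image-level loss matches its hand-derived values", {
  # perfect: some pixel certain for each present class
  S <- array(0, c(2, 2, 2))
  S[, , 1] <- c(1, 0, 1, 1); S[, , 2] <- c(0, 1, 0, 0)
  expect_equal(image_level_loss(S, rbind(c(1, 2))), 0)

  # no points, ear entirely absent
  S0 <- array(0, c(2, 2, 2)); S0[, , 1] <- 1
  expect_equal(image_level_loss(S0, NULL), 0)

  # hand evaluation: max bg 0.9, max ear 0.8, points present
  Sh <- array(0, c(2, 2, 2))
  Sh[, , 2] <- c(0.1, 0.8, 0.25, 0.5); Sh[, , 1] <- 1 - Sh[, , 2]
  expect_equal(image_level_loss(Sh, rbind(c(2, 1))), -(log(0.9) + log(0.8)) / 2)

  # no points but a confident ear pixel: -log(bg max) - log(1 - ear max)
  expect_equal(image_level_loss(Sh, NULL), -log(0.9) - log(1 - 0.8))
})

test_that("point-level loss is the negative log ear probability at the points", {
  S <- array(0, c(3, 3, 2)); S[, , 2] <- 1
  expect_equal(point_level_loss(S, rbind(c(1, 1), c(3, 3))), 0)

  S2 <- array(0.5, c(3, 3, 2))
  expect_equal(point_level_loss(S2, rbind(c(2, 2))), log(2))

  set.seed(5)
  p <- matrix(runif(9, 0.05, 0.95), 3, 3)
  S3 <- array(0, c(3, 3, 2)); S3[, , 2] <- p; S3[, , 1] <- 1 - p
  pts <- rbind(c(1, 2), c(2, 2), c(3, 1), c(3, 3), c(2, 3))
  manual <- 0
  for (i in seq_len(nrow(pts))) manual <- manual - log(p[pts[i, 1], pts[i, 2]])
  expect_equal(point_level_loss(S3, pts), manual)
  expect_equal(point_level_loss(S3, NULL), 0)
})

test_that("split loss weights boundary pixels by their blob's point count", {
  S <- array(0.5, c(3, 3, 2))
  E0 <- matrix(FALSE, 3, 3)
  lab <- structure(list(labels = matrix(1, 3, 3), points_per_blob = 2L),
                   class = "blob_labeling")
  expect_equal(split_loss(S, E0, lab), 0)

  Sb <- array(0, c(3, 3, 2)); Sb[, , 1] <- 1
  E1 <- matrix(FALSE, 3, 3); E1[2, 2] <- TRUE
  expect_equal(split_loss(Sb, E1, lab), 0)      # -log(1) = 0

  E3 <- matrix(FALSE, 3, 3); E3[1, 1] <- E3[2, 2] <- E3[3, 3] <- TRUE
  expect_equal(split_loss(S, E3, lab), 2 * 3 * log(2))
  # printed variant: plain mean of the background probability over E
  expect_equal(split_loss(S, E3, lab, variant = "printed"), 0.5)
})

test_that("false-positive loss covers exactly the pointless blobs", {
  mask <- matrix(0, 6, 6); mask[2, 2:3] <- 1; mask[5, 5] <- 1
  S <- two_level_pmap(mask, 0.8, 0.2)
  # both blobs annotated -> 0
  lab_all <- blob_labeling(S, rbind(c(2, 2), c(5, 5)))
  expect_equal(false_positive_loss(S, lab_all), 0)

  # 4-pixel pointless blob with background probability e^-1 -> exactly 4
  m2 <- matrix(0, 4, 4); m2[2:3, 2:3] <- 1
  S2 <- array(0, c(4, 4, 2))
  S2[, , 1] <- ifelse(m2 == 1, exp(-1), 0.9)
  S2[, , 2] <- 1 - S2[, , 1]
  expect_equal(false_positive_loss(S2, blob_labeling(S2, NULL)), 4)

  # random map against a per-pixel loop oracle
  set.seed(11)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  S3 <- array(0, c(8, 8, 2)); S3[, , 2] <- p; S3[, , 1] <- 1 - p
  pts <- rbind(c(1, 1))
  lab <- blob_labeling(S3, pts)
  manual <- 0
  fp <- which(lab$points_per_blob == 0)
  for (i in 1:8) for (j in 1:8)
    if (lab$labels[i, j] %in% fp && lab$labels[i, j] > 0)
      manual <- manual - log(1 - p[i, j])
  expect_equal(false_positive_loss(S3, lab), manual)
})

# A "perfect" probability map for a point set: one small confident blob per
# point, confident background elsewhere.
perfect_map <- function(points, shape, eps = 1e-4) {
  mask <- write_point_mask(points, shape)
  two_level_pmap(mask, 1 - eps, eps)
}

test_that("the total LC loss is the sum of its terms and vanishes at perfection", {
  pts <- rbind(c(2, 2), c(6, 6), c(3, 7))
  S <- perfect_map(pts, c(8, 8), eps = 1e-9)
  lb <- lc_loss(S, pts)
  expect_lt(lb$total, 1e-6)

  # exact-zero construction
  S0 <- array(0, c(8, 8, 2)); S0[, , 1] <- 1
  for (i in seq_len(nrow(pts))) { S0[pts[i, 1], pts[i, 2], 2] <- 1
                                  S0[pts[i, 1], pts[i, 2], 1] <- 0 }
  lb0 <- lc_loss(S0, pts)
  expect_equal(lb0$total, 0)
  expect_equal(lb0$image_level + lb0$point_level + lb0$split + lb0$false_positive, 0)

  # loss decreases monotonically along the perfect family as eps -> 0
  tot <- sapply(c(0.2, 0.05, 0.01, 1e-3, 1e-5), function(e)
    lc_loss(perfect_map(pts, c(8, 8), e), pts)$total)
  expect_true(all(diff(tot) < 0))
  expect_lt(tail(tot, 1), 1e-3)
})

test_that("the uniform 4x4 fixture reproduces its hand-computed breakdown", {
  S <- array(0.5, c(4, 4, 2))
  pts <- rbind(c(2, 2), c(3, 3))
  lb <- lc_loss(S, pts)
  # ties at 0.5 go to background: no blobs at all
  expect_equal(lb$image_level, log(2))        # -(log .5 + log .5)/2
  expect_equal(lb$point_level, 2 * log(2))
  expect_equal(lb$split, 0)
  expect_equal(lb$false_positive, 0)
  expect_equal(lb$total, 3 * log(2))
  expect_gte(lb$total, max(lb$image_level, lb$point_level, lb$split, lb$false_positive))
})

test_that("total equals the sum of terms on structured random maps", {
  set.seed(23)
  for (rep in 1:4) {
    p <- matrix(runif(100, 0.05, 0.95), 10, 10)
    S <- array(0, c(10, 10, 2)); S[, , 2] <- p; S[, , 1] <- 1 - p
    pts <- unique(cbind(sample(10, 4, TRUE), sample(10, 4, TRUE)))
    lb <- lc_loss(S, pts)
    expect_equal(lb$total,
                 lb$image_level + lb$point_level + lb$split + lb$false_positive)
    expect_true(all(unlist(lb) >= 0))
  }
})

fd_grad <- function(f, S, h = 1e-6) {
  g <- array(0, dim(S))
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) for (k in 1:2) {
    Sp <- S; Sp[i, j, k] <- Sp[i, j, k] + h
    Sm <- S; Sm[i, j, k] <- Sm[i, j, k] - h
    g[i, j, k] <- (f(Sp) - f(Sm)) / (2 * h)
  }
  g
}

test_that("analytic gradients of every term match finite differences", {
  set.seed(31)
  p <- matrix(runif(36, 0.15, 0.85), 6, 6)
  # carve clear structure: a two-point blob and a pointless blob
  p[2:3, 2:5] <- runif(8, 0.7, 0.85)
  p[5, 5:6] <- runif(2, 0.75, 0.85)
  S <- array(0, c(6, 6, 2)); S[, , 2] <- p; S[, , 1] <- 1 - p
  pts <- rbind(c(2, 2), c(3, 5))
  for (term in c("image_level", "point_level", "split", "false_positive", "total")) {
    str <- earcount:::lc_structure(probability_map(S), pts, 8)
    f <- switch(term,
      image_level = function(X) image_level_loss(X, pts),
      point_level = function(X) point_level_loss(X, pts),
      split = function(X) split_loss(X, str$E, str$labeling),
      false_positive = function(X) false_positive_loss(X, str$labeling),
      total = function(X) {
        lb <- lc_loss(X, pts, structure = str); lb$total
      })
    g_an <- lc_loss_grad(S, pts, term = term, structure = str)
    g_fd <- fd_grad(f, S)
    expect_lt(max(abs(g_an - g_fd)), 1e-4)
  }
})

test_that("the logit gradient agrees with chaining dL/dS through the softmax", {
  set.seed(37)
  Z <- array(rnorm(72, sd = 1.5), c(6, 6, 2))
  S <- earcount:::softmax2(Z)
  pts <- rbind(c(2, 2), c(5, 5))
  str <- earcount:::lc_structure(S, pts, 8)
  dZ_direct <- earcount:::lc_loss_dZ(S, pts, structure = str)
  dZ_chain <- earcount:::softmax_backward(S, lc_loss_grad(S, pts, structure = str))
  expect_lt(max(abs(dZ_direct - dZ_chain)), 1e-8)
})
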