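# Red-frame detection and rectification, annotated resizing, and the
# flip/rotation augmentation with annotation transport.

test_that("red-frame corners are recovered within 2 px on seeded frames", {
  errs <- sapply(1:50, function(i) {
    set.seed(i)
    ang <- if (i %% 2 == 0) runif(1, -15, 15) * pi / 180 else 0
    cfg <- field_sim_config(image_size = c(128, 128), count_law = list("fixed", 3),
                            red_frame = TRUE, frame_thickness = 6,
                            frame_angle = ang, seed = 1000 + i)
    a <- simulate_image(cfg)
    qc <- detect_red_frame(a)
    max(abs(unclass(qc) - a$meta$frame_corners))
  })
  expect_lt(max(errs), 2)
})

test_that("frame detection fails loudly without red pixels", {
  img <- simulate_image(field_sim_config(image_size = c(64, 64),
                                         count_law = list("fixed", 0), seed = 2))
  px <- img$pixels; px[, , 1] <- 0   # kill the red channel entirely
  expect_error(detect_red_frame(px), "frame not found")
})

test_that("rectify with identity corners is the identity", {
  img <- simulate_image(field_sim_config(image_size = c(64, 64),
                                         count_law = list("fixed", 3), seed = 3))
  corners <- rbind(c(1, 1), c(1, 64), c(64, 64), c(64, 1))
  out <- rectify(img, corners, out_size = c(64, 64))
  expect_equal(out$pixels, img$pixels, tolerance = 1e-12)
  expect_equal(out$points[order(out$points[, 1], out$points[, 2]), ],
               img$points[order(img$points[, 1], img$points[, 2]), ])
})

test_that("rectifying an axis-aligned quad equals crop-and-resize", {
  img <- simulate_image(field_sim_config(image_size = c(64, 64),
                                         count_law = list("fixed", 2), seed = 4))
  corners <- rbind(c(11, 21), c(11, 50), c(40, 50), c(40, 21))
  got <- rectify(img$pixels, corners, out_size = c(60, 60))
  want <- crop_resize_oracle(img$pixels, 11, 40, 21, 50, 60, 60)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("the quad centre maps to the output centre", {
  # rotated convex quad around (32, 32)
  corners <- rbind(c(12, 20), c(18, 52), c(50, 45), c(45, 14))
  centre <- colMeans(corners)
  H <- earcount:::solve_homography(corners,
                                   rbind(c(1, 1), c(1, 61), c(61, 61), c(61, 1)))
  mapped <- earcount:::apply_homography(H, rbind(centre))
  expect_lt(max(abs(mapped - c(31, 31))), 1.5)
})

test_that("degenerate corners are rejected", {
  bad <- rbind(c(1, 1), c(1, 32), c(1, 64), c(64, 1))   # three collinear
  img <- array(0.5, c(64, 64, 3))
  expect_error(rectify(img, bad), "convex|degenerate")
})

test_that("resize_annotated scales points with the raster", {
  px <- array(0.5, c(128, 128, 3))
  a <- annotated_image(px, rbind(c(100, 120)), "r")
  same <- resize_annotated(a, 1)
  expect_equal(same$points, a$points)

  px2 <- array(0.5, c(400, 800, 3))
  b <- annotated_image(px2, rbind(c(100, 200)), "r2")
  small <- resize_annotated(b, 0.25)
  expect_equal(dim(small$pixels)[1:2], c(100, 200))
  expect_equal(unname(small$points), rbind(c(25L, 50L)))

  expect_error(resize_annotated(a, 0.1), "< 32")
  expect_error(resize_annotated(a, -1), "positive")
})

test_that("well-separated points survive downscaling without collisions", {
  # 400 points on a 20x20 grid with 8 px spacing: scale 0.25 keeps them apart
  gr <- as.matrix(expand.grid(row = seq(8, 160, by = 8), col = seq(8, 160, by = 8)))
  a <- annotated_image(array(0.5, c(168, 168, 3)), gr, "grid")
  expect_equal(a$count, 400)
  small <- resize_annotated(a, 0.25)
  expect_equal(small$count, 400)
})

test_that("colliding points after resize are deduplicated with a warning", {
  # rows 57 and 58 both land on output row 15 at scale 0.25
  a <- annotated_image(array(0.5, c(128, 128, 3)),
                       rbind(c(57, 57), c(58, 58)), "c")
  expect_warning(small <- resize_annotated(a, 0.25), "duplicate")
  expect_equal(small$count, 1)
})

test_that("augmentation multiplies the dataset by the mode count", {
  cfg <- field_sim_config(image_size = c(48, 48), count_law = list("uniform", 2, 6),
                          seed = 9)
  ds <- simulate_dataset(cfg, 12)
  expect_length(augment(ds, "flip"), 24)
  expect_length(augment(ds, c("flip", "rotation")), 36)
  expect_error(augment(ds, "zoom"), "modes")
  expect_error(augment(ds, character(0)), "modes")

  # per-image counts are preserved exactly, ids suffixed deterministically
  aug <- augment(ds, c("flip", "rotation"))
  for (a in ds) {
    expect_equal(aug[[paste0(a$image_id, "_flip")]]$count, a$count)
    expect_equal(aug[[paste0(a$image_id, "_rot")]]$count, a$count)
  }
})

test_that("flip is an involution and four quarter-rotations are the identity", {
  cfg <- field_sim_config(image_size = c(48, 48), count_law = list("fixed", 5),
                          seed = 11)
  a <- simulate_image(cfg)
  ff <- earcount:::flip_image(earcount:::flip_image(a))
  expect_identical(ff$pixels, a$pixels)
  expect_equal(unname(ff$points), unname(a$points))

  r <- a
  for (i in 1:4) r <- earcount:::rotate90_image(r)
  expect_identical(r$pixels, a$pixels)
  ord <- function(p) p[order(p[, 1], p[, 2]), , drop = FALSE]
  expect_equal(unname(ord(r$points)), unname(ord(a$points)))
})

test_that("flip and rotation transport annotation points with the pixels", {
  a <- simulate_image(field_sim_config(image_size = c(40, 48),
                                       count_law = list("fixed", 6), seed = 13))
  fl <- earcount:::flip_image(a)
  # a point marks the same underlying pixel value after the flip
  for (i in seq_len(a$count)) {
    p <- a$points[i, ]
    expect_equal(fl$pixels[p[1], 48 + 1 - p[2], ], a$pixels[p[1], p[2], ])
  }
  rt <- earcount:::rotate90_image(a)
  expect_equal(dim(rt$pixels)[1:2], c(48, 40))
  for (i in seq_len(a$count)) {
    p <- a$points[i, ]
    q <- c(48 + 1 - p[2], p[1])
    expect_equal(rt$pixels[q[1], q[2], ], a$pixels[p[1], p[2], ])
  }
})

test_that("the red classifier respects its HSV window", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(0.9, 0.1, 0.1)    # red
  px[1, 2, ] <- c(0.1, 0.8, 0.1)    # green
  px[1, 3, ] <- c(0.9, 0.85, 0.8)   # washed out (low saturation)
  expect_equal(red_mask(px)[1, ], c(TRUE, FALSE, FALSE))
})
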