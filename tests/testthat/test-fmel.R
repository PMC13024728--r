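test_that("normalized landmarks convert to floored, clamped pixel coordinates", {
  lm <- data.frame(index = 1:3, x = c(0.25, 0, 1.0), y = c(0.5, 0, 1.0))
  pts <- to_pixel_coords(lm[1, ], 200, 100)
  expect_equal(c(pts$x, pts$y), c(50, 50))
  pts0 <- to_pixel_coords(lm[2, ], 37, 91)
  expect_equal(c(pts0$x, pts0$y), c(0, 0))
  # floor(1.0 * 100) = 100 is out of range and must clamp to 99
  pts1 <- to_pixel_coords(lm[3, ], 100, 100)
  expect_equal(c(pts1$x, pts1$y), c(99, 99))

  expect_error(to_pixel_coords(lm[0, ], 10, 10), class = "tfm_empty_landmarks")
  expect_error(to_pixel_coords(data.frame(index = 1, x = 1.2, y = 0.5), 10, 10),
               class = "tfm_invalid_landmark")
  expect_error(to_pixel_coords(data.frame(index = 1, x = -0.01, y = 0.5), 10, 10),
               class = "tfm_invalid_landmark")
})

test_that("eye bounding box pads by the margin and clamps to the image", {
  pts <- data.frame(x = c(60, 120), y = c(40, 50))
  box <- eye_bounding_box(pts, 300, 200, margin = 50)
  expect_equal(unlist(box[c("xmin", "xmax", "ymin", "ymax")], use.names = FALSE),
               c(10, 170, 0, 100))

  one <- eye_bounding_box(data.frame(x = 5, y = 5), 100, 100, margin = 50)
  expect_equal(unlist(one[c("xmin", "xmax", "ymin", "ymax")], use.names = FALSE),
               c(0, 55, 0, 55))

  # zero margin returns the point extent
  z <- eye_bounding_box(pts, 300, 200, margin = 0)
  expect_equal(unlist(z[c("xmin", "xmax", "ymin", "ymax")], use.names = FALSE),
               c(60, 120, 40, 50))

  expect_error(eye_bounding_box(pts[0, ], 100, 100), class = "tfm_empty_landmarks")
  # all points at/above the right edge leave nothing after clamping
  expect_error(eye_bounding_box(data.frame(x = 120, y = 10), 100, 100, margin = 0),
               class = "tfm_degenerate_roi")
})

test_that("cropping takes the half-open slice and leaves the source alone", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  before <- img
  full <- crop_eye(img, list(xmin = 0, xmax = 100, ymin = 0, ymax = 100))
  expect_identical(full$pixels, img)
  small <- crop_eye(img, list(xmin = 10, xmax = 20, ymin = 30, ymax = 40))
  expect_equal(dim(small$pixels), c(10, 10))
  expect_identical(small$pixels, img[31:40, 11:20])
  expect_identical(img, before)
  expect_error(crop_eye(img, list(xmin = 10, xmax = 10, ymin = 0, ymax = 5)),
               class = "tfm_degenerate_roi")
})

test_that("eye region extraction composes conversion, box and crop", {
  img <- matrix(0, 200, 300)
  lm <- data.frame(index = c(33, 133, 362, 263),
                   x = c(60, 80, 100, 120) / 300,
                   y = c(40, 45, 48, 50) / 200)
  crop <- extract_eye_region(img, lm)
  expect_equal(dim(crop$pixels), c(100, 160))
  expect_equal(unlist(crop$box[c("xmin", "xmax", "ymin", "ymax")],
                      use.names = FALSE), c(10, 170, 0, 100))

  expect_error(extract_eye_region(img, lm[lm$index != 133, ]),
               class = "tfm_missing_landmark")
  expect_error(extract_eye_region(img, lm[0, ]),
               class = "tfm_detection_failure")
})

test_that("boxes stay inside the image and match a brute-force oracle under fuzzing", {
  set.seed(71)
  for (rep in 1:200) {
    w <- sample(20:400, 1); h <- sample(20:400, 1)
    n <- sample(1:8, 1); m <- sample(1:80, 1)
    px <- sample(0:(w - 1), n, replace = TRUE)
    py <- sample(0:(h - 1), n, replace = TRUE)
    box <- eye_bounding_box(data.frame(x = px, y = py), w, h, m)
    expect_true(box$xmin >= 0 && box$xmin < box$xmax && box$xmax <= w)
    expect_true(box$ymin >= 0 && box$ymin < box$ymax && box$ymax <= h)
    oracle <- brute_box(px, py, w, h, m)
    expect_equal(unlist(box[names(oracle)], use.names = FALSE),
                 unname(oracle))
  }
})

test_that("growing the margin never shrinks the box", {
  set.seed(72)
  pts <- data.frame(x = sample(10:290, 5), y = sample(10:190, 5))
  margins <- c(0, 5, 20, 50, 120)
  boxes <- lapply(margins, function(m) eye_bounding_box(pts, 300, 200, m))
  for (k in 2:length(boxes)) {
    expect_lte(boxes[[k]]$xmin, boxes[[k - 1]]$xmin)
    expect_gte(boxes[[k]]$xmax, boxes[[k - 1]]$xmax)
    expect_lte(boxes[[k]]$ymin, boxes[[k - 1]]$ymin)
    expect_gte(boxes[[k]]$ymax, boxes[[k - 1]]$ymax)
  }
})

test_that("re-extracting a crop with the same landmarks and margin is idempotent", {
  set.seed(73)
  img <- matrix(runif(200 * 300, 0, 255), 200, 300)
  lm <- data.frame(index = c(33, 133, 362, 263),
                   x = c(0.2, 0.3, 0.4, 0.5), y = c(0.2, 0.25, 0.25, 0.3))
  cfg <- eye_landmark_config(margin = 10)
  crop1 <- extract_eye_region(img, lm, cfg)
  # same landmarks expressed relative to the crop; the half-pixel offset
  # keeps floor() robust to floating-point round-off
  pts <- to_pixel_coords(lm, 300, 200)
  rel <- data.frame(index = pts$index,
                    x = (pts$x - crop1$box$xmin + 0.5) / ncol(crop1$pixels),
                    y = (pts$y - crop1$box$ymin + 0.5) / nrow(crop1$pixels))
  crop2 <- extract_eye_region(crop1$pixels, rel, cfg)
  expect_identical(crop2$pixels, crop1$pixels)
})
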