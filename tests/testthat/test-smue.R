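test_that("contour centroid is the raw-moment mean of the points", {
  sq <- data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  c1 <- contour_centroid(sq)
  expect_equal(c(c1$cx, c1$cy), c(1, 1))
  tri <- data.frame(x = c(0, 3, 0), y = c(0, 0, 3))
  c2 <- contour_centroid(tri)
  expect_equal(c(c2$cx, c2$cy), c(1, 1))
  expect_equal(c(c2$m00, c2$m10, c2$m01), c(3, 3, 3))
  expect_error(contour_centroid(sq[1:2, ]), class = "tfm_insufficient_contour")
})

test_that("maximum radius takes the ceiling of Dmax plus beta", {
  ctr <- list(cx = 0, cy = 0)
  g <- max_radius(data.frame(x = c(3, 0), y = c(4, 1)), ctr,
                  smue_config(beta = 2))
  expect_equal(g$Dmax, 5)
  expect_equal(g$Rmax, 7)
  g2 <- max_radius(data.frame(x = 2.5, y = 0), ctr, smue_config(beta = 0))
  expect_equal(g2$Rmax, 3)
  g3 <- max_radius(data.frame(x = 4, y = 0), ctr, smue_config(beta = 0))
  expect_equal(g3$Rmax, 4)
  expect_error(max_radius(data.frame(x = 0, y = 0), ctr, smue_config(beta = 0)),
               class = "tfm_degenerate_geometry")
})

make_geometry <- function(cx, cy, Rmax, H = 32L, W = 32L) {
  structure(list(cx = cx, cy = cy, Dmax = Rmax, beta = 0, Rmax = Rmax,
                 H = H, W = W), class = "unwrap_geometry")
}

test_that("unwrapping fixed fields behaves as the polar sampling formula", {
  g <- make_geometry(20, 20, 15)
  const <- matrix(7, 41, 41)
  expect_true(all(unwrap_eye(const, g, "lower")$U == 7))

  # radius zero: the whole first row is the center intensity
  img <- matrix(runif(41 * 41, 0, 255), 41)
  u <- unwrap_eye(img, g, "upper")$U
  expect_true(all(u[1, ] == img[21, 21]))

  # intensity equal to the x coordinate reads back cx + r cos(theta)
  ramp <- matrix(rep(0:40, each = 41), 41)
  ur <- unwrap_eye(ramp, g, "lower")$U
  r <- seq(0, 15, length.out = 32)
  theta <- seq(0, pi, length.out = 32)
  expected <- 20 + outer(r, cos(theta))
  expect_lt(max(abs(ur - expected)), 0.5)
})

test_that("vectorized unwrap agrees with the per-pixel brute-force sampler", {
  set.seed(11)
  for (rep in 1:20) {
    w <- sample(25:60, 1); h <- sample(25:60, 1)
    img <- matrix(runif(w * h, 0, 255), h, w)
    g <- make_geometry(cx = runif(1, 8, w - 8), cy = runif(1, 8, h - 8),
                       Rmax = sample(5:20, 1),
                       H = sample(8:24, 1), W = sample(8:24, 1))
    hemi <- sample(c("upper", "lower"), 1)
    expect_equal(unwrap_eye(img, g, hemi)$U, brute_unwrap(img, g, hemi),
                 tolerance = 1e-9)
  }
})

test_that("radially decreasing phantoms unwrap to columns non-increasing in radius", {
  g <- make_geometry(30, 30, 25, H = 40L, W = 24L)
  xs <- matrix(rep(0:60, each = 61), 61) - 30
  ys <- matrix(rep(0:60, times = 61), 61) - 30
  radial <- 255 - 3 * sqrt(xs^2 + ys^2)
  for (hemi in c("upper", "lower")) {
    U <- unwrap_eye(radial, g, hemi)$U
    expect_true(all(diff(U) <= 1e-9))
  }
})

test_that("boundary points map to the unwrapped frame by angle and radius", {
  g <- make_geometry(50, 50, 20, H = 64L, W = 128L)
  pts <- data.frame(label = c("a", "b", "c"),
                    x = c(50 + 10, 50 - 10, 50),
                    y = c(50, 50, 50 + 20))
  uv <- map_boundary_points(pts, g)
  expect_equal(uv$u, c(0, 127, 127 / 2))
  expect_equal(uv$v[3], 63)
  expect_equal(uv$hemisphere, c("upper", "upper", "lower"))
  expect_equal(uv$r, c(10, 10, 20))
  expect_error(
    map_boundary_points(data.frame(label = "z", x = 50, y = 50), g),
    class = "tfm_degenerate_geometry")
})

step_raster <- function(steps, H = 64L, W = 16L) {
  # steps: named vector row -> value change boundaries built outside
  U <- matrix(steps, nrow = H, ncol = W)
  structure(list(U = U, hemisphere = "lower",
                 geometry = make_geometry(0, 0, 1, H, W)),
            class = "unwrapped_eye")
}

test_that("iris onset sits at the intensity step, breaking ties toward the eyelid", {
  prof <- c(rep(200, 30), rep(50, 34))
  y1 <- detect_iris_onset(step_raster(prof), u = 4, v = 50)
  expect_true(abs(y1 - 30) <= 1)

  expect_error(detect_iris_onset(step_raster(rep(120, 64)), u = 4, v = 50),
               class = "tfm_no_boundary_found")

  two <- c(rep(200, 20), rep(140, 20), rep(80, 24))
  y2 <- detect_iris_onset(step_raster(two), u = 4, v = 50)
  expect_equal(y2, 40)

  expect_error(detect_iris_onset(step_raster(prof), u = 4, v = 2),
               class = "tfm_degenerate_geometry")
})

test_that("scleral distances are |v - y*| with missing positions flagged", {
  prof <- c(rep(220, 30), rep(40, 34))
  lower <- step_raster(prof)
  flat <- step_raster(rep(120, 64))
  uv <- data.frame(label = c("L0", "L1"), u = c(4, 4), v = c(50, 50),
                   hemisphere = c("lower", "upper"))
  p <- sclera_distances(flat, lower, uv, smue_config(), side = "left")
  expect_equal(p$distance[1], abs(50 - 30))
  expect_equal(p$status, c("ok", "missing"))
  expect_true(is.na(p$distance[2]))

  # coincident boundary: y* at v gives distance 0
  uv0 <- data.frame(label = "L0", u = 4, v = 30, hemisphere = "lower")
  p0 <- sclera_distances(flat, lower, uv0, smue_config(), side = "left")
  expect_lte(p0$distance[1], 1)
})

test_that("the full engine recovers phantom distances within two unwrapped pixels", {
  ph <- make_eye_phantom()
  res <- run_smue(ph$image, ph$contour, ph$points, side = ph$side)
  m <- merge(res$profile, ph$truth, by = "label")
  expect_equal(nrow(m), 12)
  expect_true(all(m$status == "ok"))
  expect_lt(max(abs(m$distance - m$d_true)), 2)

  # default reference point placement hits the same contour vertices
  res2 <- run_smue(ph$image, ph$contour, side = ph$side)
  expect_lt(max(abs(sort(res2$profile$distance) - sort(ph$truth$d_true))), 2)

  expect_error(run_smue(ph$image, ph$contour[1:2, ], ph$points),
               class = "tfm_insufficient_contour")
})

test_that("mirror-image phantoms give mirrored profiles", {
  ph <- make_eye_phantom(eyelid_radii = c(55, 46, 40))
  n <- ncol(ph$image)
  mir_img <- ph$image[, n:1]
  mir_contour <- data.frame(x = n - 1 - ph$contour$x, y = ph$contour$y)
  mir_pts <- data.frame(label = ph$points$label,
                        x = n - 1 - ph$points$x, y = ph$points$y)
  a <- run_smue(ph$image, ph$contour, ph$points)$profile
  b <- run_smue(mir_img, mir_contour, mir_pts)$profile
  expect_equal(sort(a$distance), sort(b$distance), tolerance = 1e-8)
})

test_that("rotating a phantom by 90 degrees permutes but preserves the distance multiset", {
  ph <- make_eye_phantom(eyelid_radii = c(55, 46, 40))
  n <- nrow(ph$image)
  # 90 degree rotation in row/col space: (x, y) -> (n-1-y, x)
  rot_img <- t(ph$image[n:1, ])
  rot_contour <- data.frame(x = n - 1 - ph$contour$y, y = ph$contour$x)
  rot_pts <- data.frame(label = ph$points$label,
                        x = n - 1 - ph$points$y, y = ph$points$x)
  a <- run_smue(ph$image, ph$contour, ph$points)$profile
  b <- run_smue(rot_img, rot_contour, rot_pts)$profile
  expect_equal(sort(a$distance), sort(b$distance), tolerance = 1)
})
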