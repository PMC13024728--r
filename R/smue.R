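#' Sclera map unwrapping: configuration and geometry
#'
#' The ocular surface around the pupil center is resampled onto a polar
#' (rubber-sheet) raster: rows index radius from 0 to `Rmax`, columns index
#' the half-circle angle from 0 to pi. Because the angular coordinate only
#' spans a half circle, each eye yields two rasters, one per hemisphere
#' (upper and lower eyelid); the sign of the vertical offset from the center
#' decides the hemisphere of every boundary point.
#'
#' @param beta radial slack in pixels added to the maximum center-to-contour
#'   distance before taking the ceiling (`Rmax = ceil(Dmax + beta)`), so the
#'   eyelid boundary never sits on the raster edge. Default 5.
#' @param H,W rows (radial samples) and columns (angular samples) of each
#'   unwrapped raster. Default 128 x 128.
#' @param omega_a,omega_b window sizes in unwrapped rows for the means above
#'   and below a candidate row in iris-onset detection. Default 3; set 1 for
#'   single-pixel lookups.
#' @param min_contrast minimum intensity contrast (8-bit scale) for an iris
#'   onset to count as found; flat columns report a missing boundary rather
#'   than an arbitrary row. Default 10.
#' @return a list of class `smue_config`.
#' @export
smue_config <- function(beta = 5, H = 128L, W = 128L,
                        omega_a = 3L, omega_b = 3L, min_contrast = 10) {
  tfm_abort_if(beta < 0, "invalid_spec", "beta must be >= 0")
  tfm_abort_if(H < 2 || W < 2, "invalid_spec", "unwrapped raster needs H >= 2, W >= 2")
  tfm_abort_if(omega_a < 1 || omega_b < 1, "invalid_spec",
    "omega_a and omega_b must be >= 1")
  structure(list(beta = beta, H = as.integer(H), W = as.integer(W),
                 omega_a = as.integer(omega_a), omega_b = as.integer(omega_b),
                 min_contrast = min_contrast),
            class = "smue_config")
}

#' Centroid of an eyelid contour
#'
#' Raw moments over the binary point set: `m00` is the point count, `m10` and
#' `m01` the coordinate sums; the center is `(m10/m00, m01/m00)`. This stands
#' in for the pupil center in the unwrap geometry.
#'
#' @param contour data frame with 0-based pixel columns `x`, `y` (at least 3
#'   points).
#' @return a list of class `pupil_center` with `cx`, `cy` and the raw moments.
#' @export
contour_centroid <- function(contour) {
  contour <- as.data.frame(contour)
  tfm_abort_if(nrow(contour) < 3L, "insufficient_contour",
    "contour needs at least 3 points")
  m00 <- nrow(contour)
  m10 <- sum(contour$x)
  m01 <- sum(contour$y)
  structure(list(cx = m10 / m00, cy = m01 / m00,
                 m00 = m00, m10 = m10, m01 = m01),
            class = "pupil_center")
}

#' Unwrap geometry from a contour and center
#'
#' `Dmax` is the largest Euclidean distance from the center to any contour
#' point and `Rmax = ceil(Dmax + beta)` is the radial extent of the unwrapped
#' raster.
#'
#' @param contour data frame with pixel columns `x`, `y`.
#' @param center a [contour_centroid()] result (or list with `cx`, `cy`).
#' @param config an [smue_config()] supplying `beta`, `H`, `W`.
#' @return a list of class `unwrap_geometry` with `cx`, `cy`, `Dmax`, `beta`,
#'   `Rmax`, `H`, `W`.
#' @export
max_radius <- function(contour, center, config = smue_config()) {
  contour <- as.data.frame(contour)
  tfm_abort_if(nrow(contour) == 0L, "insufficient_contour", "contour is empty")
  d <- sqrt((contour$x - center$cx)^2 + (contour$y - center$cy)^2)
  Dmax <- max(d)
  tfm_abort_if(Dmax == 0 && config$beta == 0, "degenerate_geometry",
    "all contour points coincide with the center and beta = 0")
  structure(list(cx = center$cx, cy = center$cy, Dmax = Dmax,
                 beta = config$beta, Rmax = ceiling(Dmax + config$beta),
                 H = config$H, W = config$W),
            class = "unwrap_geometry")
}

#' Polar (rubber-sheet) unwrap of one ocular hemisphere
#'
#' Row `i` of the output samples radius `r_i = i / (H - 1) * Rmax`, column `j`
#' angle `theta_j = j / (W - 1) * pi`. Sampling positions are
#' `x = cx + r cos(theta)` and `y = cy + r sin(theta)` for the lower
#' hemisphere or `y = cy - r sin(theta)` for the upper one (image rows grow
#' downward). Intensities are bilinearly interpolated with edge clamping;
#' color crops are converted to grayscale first.
#'
#' @param crop an `eye_crop` or a raster (see [raster-conventions]).
#' @param geometry an `unwrap_geometry` (see [max_radius()]).
#' @param hemisphere `"upper"` or `"lower"`.
#' @return a list of class `unwrapped_eye` with the `H x W` matrix `U`, the
#'   `geometry` and the `hemisphere`.
#' @export
unwrap_eye <- function(crop, geometry, hemisphere = c("lower", "upper")) {
  hemisphere <- match.arg(hemisphere)
  img <- if (inherits(crop, "eye_crop")) crop$pixels else crop
  gray <- as_gray(img)
  H <- geometry$H; W <- geometry$W
  r <- seq(0, geometry$Rmax, length.out = H)
  theta <- seq(0, pi, length.out = W)
  sgn <- if (hemisphere == "lower") 1 else -1
  xs <- geometry$cx + outer(r, cos(theta))
  ys <- geometry$cy + sgn * outer(r, sin(theta))
  U <- matrix(bilinear_sample(gray, as.vector(xs), as.vector(ys)), nrow = H)
  structure(list(U = U, geometry = geometry, hemisphere = hemisphere),
            class = "unwrapped_eye")
}

#' Map labeled eyelid boundary points into unwrapped coordinates
#'
#' For each point, the offset from the center gives the radius
#' `r = sqrt(dx^2 + dy^2)` and half-circle angle
#' `theta = arccos(dx / r) in [0, pi]`; the unwrapped column is
#' `u = theta / pi * (W - 1)` and the row `v = clamp(r / Rmax, 0, 1) * (H - 1)`.
#' Points below the center (`dy > 0`, image rows grow downward) belong to the
#' lower hemisphere, all others to the upper one.
#'
#' @param points data frame with columns `label`, `x`, `y` (0-based pixels).
#' @param geometry an `unwrap_geometry`.
#' @return data frame with columns `label`, `x`, `y`, `dx`, `dy`, `r`,
#'   `theta`, `u`, `v`, `hemisphere`.
#' @export
map_boundary_points <- function(points, geometry) {
  points <- as.data.frame(points)
  dx <- points$x - geometry$cx
  dy <- points$y - geometry$cy
  r <- sqrt(dx^2 + dy^2)
  tfm_abort_if(any(r == 0), "degenerate_geometry",
    "boundary point coincides with the unwrap center")
  theta <- acos(pmin(pmax(dx / r, -1), 1))
  data.frame(
    label = points$label,
    x = points$x, y = points$y,
    dx = dx, dy = dy, r = r, theta = theta,
    u = theta / pi * (geometry$W - 1),
    v = pmin(pmax(r / geometry$Rmax, 0), 1) * (geometry$H - 1),
    hemisphere = ifelse(dy > 0, "lower", "upper"),
    stringsAsFactors = FALSE
  )
}

#' Locate the iris onset along one unwrapped column
#'
#' Walks the column nearest to `u` outward from the center and scores each
#' candidate row `y` by the absolute difference between the mean intensity of
#' the `omega_a` rows above (`[y - omega_a, y - 1]`) and the `omega_b` rows
#' below (`[y + 1, y + omega_b]`, truncated at the raster edge). The onset
#' `y*` is the row of maximum contrast within `[omega_a, v - 1]`; ties break
#' toward the larger row (closer to the eyelid).
#'
#' @param unwrapped an `unwrapped_eye`.
#' @param u,v unwrapped column and row of the boundary point (0-based, may be
#'   fractional).
#' @param config an [smue_config()].
#' @return integer row `y*` (0-based).
#' @export
detect_iris_onset <- function(unwrapped, u, v, config = smue_config()) {
  U <- unwrapped$U
  H <- nrow(U)
  j <- min(max(round_half_up(u), 0), ncol(U) - 1)
  col <- U[, j + 1]
  ya <- config$omega_a
  yb <- min(round_half_up(v) - 1, H - 2)
  tfm_abort_if(yb < ya, "degenerate_geometry",
    "empty iris-onset search range (boundary too close to the center)")
  ys <- ya:yb
  contrast <- vapply(ys, function(y) {
    above <- col[(y - config$omega_a):(y - 1) + 1]
    below <- col[(y + 1):min(y + config$omega_b, H - 1) + 1]
    abs(mean(above) - mean(below))
  }, numeric(1))
  best <- max(contrast)
  if (best < config$min_contrast) {
    tfm_error("no_boundary_found",
      sprintf("maximum contrast %.2f below min_contrast %.2f", best,
              config$min_contrast))
  }
  ys[max(which(contrast == best))]
}

#' Scleral distances at the twelve reference positions
#'
#' For each boundary point the iris onset `y*` is located in the raster of
#' the point's own hemisphere and the scleral distance is `d = |v - y*|` in
#' unwrapped rows. Positions whose column shows no detectable onset are
#' recorded as missing rather than zero, and do not abort the profile.
#'
#' @param upper,lower `unwrapped_eye` rasters for the two hemispheres.
#' @param uv boundary points from [map_boundary_points()].
#' @param config an [smue_config()].
#' @param side `"left"` or `"right"`.
#' @return a [sclera_profile()] with one row per reference point.
#' @export
sclera_distances <- function(upper, lower, uv, config = smue_config(),
                             side = c("left", "right")) {
  side <- match.arg(side)
  n <- nrow(uv)
  y_star <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (k in seq_len(n)) {
    ras <- if (uv$hemisphere[k] == "lower") lower else upper
    y_star[k] <- tryCatch(
      detect_iris_onset(ras, uv$u[k], uv$v[k], config),
      tfm_no_boundary_found = function(e) { status[k] <<- "missing"; NA_real_ }
    )
  }
  sclera_profile(
    side = side,
    labels = as.character(uv$label),
    distances = abs(uv$v - y_star),
    status = status,
    details = data.frame(uv, y_star = y_star)
  )
}

# Intersect a ray from `center` in direction `dir` with the closed contour
# polygon (piecewise-linear); returns the outermost intersection point.
ray_contour_intersection <- function(contour, center, dir) {
  px <- c(contour$x, contour$x[1])
  py <- c(contour$y, contour$y[1])
  best_t <- -Inf
  for (k in seq_len(length(px) - 1)) {
    ex <- px[k + 1] - px[k]; ey <- py[k + 1] - py[k]
    den <- dir[1] * (-ey) - dir[2] * (-ex)
    if (abs(den) < 1e-12) next
    qx <- px[k] - center$cx; qy <- py[k] - center$cy
    t <- (qx * (-ey) + qy * ex) / den
    s <- (dir[1] * qy - dir[2] * qx) / den
    if (t > 1e-9 && s >= -1e-9 && s <= 1 + 1e-9) best_t <- max(best_t, t)
  }
  if (!is.finite(best_t)) {
    tfm_error("degenerate_geometry",
      "a reference ray does not intersect the eyelid contour")
  }
  c(center$cx + best_t * dir[1], center$cy + best_t * dir[2])
}

#' Default placement of the twelve reference points
#'
#' Six rays per hemisphere at half-circle angles `(j + 0.5) * pi / 6`,
#' `j = 0..5`, intersected with the eyelid contour polygon. Labels follow the
#' around-the-eye order upper eyelid, corner, lower eyelid: positions 0--5
#' run along the upper eyelid with increasing angle and 6--11 back along the
#' lower eyelid with decreasing angle.
#'
#' @param contour data frame with pixel columns `x`, `y` (ordered polygon).
#' @param center a [contour_centroid()] result.
#' @param side `"left"` or `"right"` (controls the `L`/`R` label prefix).
#' @return data frame with columns `label`, `x`, `y`.
#' @export
default_reference_points <- function(contour, center,
                                     side = c("left", "right")) {
  side <- match.arg(side)
  prefix <- if (side == "left") "L" else "R"
  contour <- as.data.frame(contour)
  ang <- (seq_len(6) - 0.5) * pi / 6
  upper <- lapply(ang, function(th)
    ray_contour_intersection(contour, center, c(cos(th), -sin(th))))
  lower <- lapply(rev(ang), function(th)
    ray_contour_intersection(contour, center, c(cos(th), sin(th))))
  pts <- do.call(rbind, c(upper, lower))
  data.frame(label = paste0(prefix, 0:11), x = pts[, 1], y = pts[, 2],
             stringsAsFactors = FALSE)
}

#' Run the full sclera map unwrapping engine on one eye
#'
#' Composes [contour_centroid()], [max_radius()], [unwrap_eye()] for both
#' hemispheres, [map_boundary_points()] and [sclera_distances()]. The result
#' is deterministic for fixed inputs.
#'
#' @param crop an `eye_crop` or raster of the periocular region.
#' @param contour data frame of eyelid boundary points (`x`, `y`, 0-based
#'   pixels, ordered around the eye).
#' @param reference_points optional data frame `label`, `x`, `y`; if `NULL`
#'   the twelve [default_reference_points()] are used.
#' @param config an [smue_config()].
#' @param side `"left"` or `"right"`.
#' @return a list of class `smue_result`: `profile` (a [sclera_profile()]),
#'   `upper` and `lower` unwrapped rasters, `geometry` and the mapped `uv`
#'   table.
#' @export
run_smue <- function(crop, contour, reference_points = NULL,
                     config = smue_config(), side = c("left", "right")) {
  side <- match.arg(side)
  center <- contour_centroid(contour)
  geometry <- max_radius(contour, center, config)
  upper <- unwrap_eye(crop, geometry, "upper")
  lower <- unwrap_eye(crop, geometry, "lower")
  if (is.null(reference_points)) {
    reference_points <- default_reference_points(contour, center, side)
  }
  uv <- map_boundary_points(reference_points, geometry)
  profile <- sclera_distances(upper, lower, uv, config, side)
  structure(list(profile = profile, upper = upper, lower = lower,
                 geometry = geometry, uv = uv),
            class = "smue_result")
}

#' @export
print.smue_result <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<smue_result> center (%.2f, %.2f), Dmax %.2f, Rmax %d, raster %d x %d\n",
              g$cx, g$cy, g$Dmax, g$Rmax, g$H, g$W))
  print(x$profile)
  invisible(x)
}
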