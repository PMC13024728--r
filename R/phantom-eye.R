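#' Synthetic eye phantom with analytic scleral distances
#'
#' Renders a stylized eye on a skin background: concentric pupil and iris
#' discs inside an eyelid region whose radius varies with angle. The twelve
#' eyelid reference points sit at full-circle angles `(j + 0.5) * 30` degrees
#' with radii mirrored across both axes, so the contour centroid coincides
#' with the disc center exactly and the scleral distance at every position
#' has the closed form `d = (r_j - iris_radius) / Rmax * (H - 1)` in
#' unwrapped rows, for the same `beta` and `H` the measurement engine uses.
#' Edges are rendered binary (no anti-aliasing) to keep that truth exact.
#'
#' @param size square image side in pixels.
#' @param center length-2 center `(x, y)`; defaults to the image center.
#' @param iris_radius,pupil_radius disc radii in pixels
#'   (`pupil < iris < min(eyelid)`).
#' @param eyelid_radii either 3 radii (one per mirrored angle group, expanded
#'   to all 12 positions) or all 12; 12 values must be mirror-symmetric so
#'   the centroid stays on the center.
#' @param intensities named vector with `sclera`, `iris`, `pupil`, `skin`
#'   on the 8-bit scale, pairwise separated by at least 4 noise standard
#'   deviations.
#' @param noise_sd additive Gaussian pixel noise, default 0.
#' @param seed optional RNG seed applied before noise is drawn.
#' @param side `"left"` or `"right"` (label prefix).
#' @param config [smue_config()] whose `beta` and `H` the analytic truth is
#'   computed for.
#' @return a list of class `eye_phantom`: `image` (grayscale matrix),
#'   `contour` (the 12 boundary points in circular order), `points` (labeled
#'   reference points), `truth` (data frame `label`, `d_true`), `geometry`
#'   facts (`Rmax`, radii) and the spec echo.
#' @export
make_eye_phantom <- function(size = 200L,
                             center = NULL,
                             iris_radius = 20,
                             pupil_radius = 8,
                             eyelid_radii = c(55, 48, 42),
                             intensities = c(sclera = 230, iris = 60,
                                             pupil = 20, skin = 150),
                             noise_sd = 0,
                             seed = NULL,
                             side = c("left", "right"),
                             config = smue_config()) {
  side <- match.arg(side)
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  ang <- (0:11 + 0.5) * pi / 6  # full-circle angles of the 12 positions
  group <- c(1, 2, 3, 3, 2, 1, 1, 2, 3, 3, 2, 1)
  if (length(eyelid_radii) == 3L) {
    radii <- eyelid_radii[group]
  } else if (length(eyelid_radii) == 12L) {
    radii <- eyelid_radii
    sym <- abs(sum(radii * cos(ang))) < 1e-9 && abs(sum(radii * sin(ang))) < 1e-9
    tfm_abort_if(!sym, "invalid_spec",
      "12 eyelid radii must be mirror-symmetric (centroid on the center)")
  } else {
    tfm_error("invalid_spec", "eyelid_radii must have length 3 or 12")
  }
  tfm_abort_if(!(pupil_radius < iris_radius && iris_radius <= min(radii)),
    "invalid_spec", "need pupil_radius < iris_radius <= min(eyelid_radii)")
  tfm_abort_if(noise_sd > 0 && min(dist(intensities)) < 4 * noise_sd,
    "invalid_spec", "intensities must be separated by at least 4 * noise_sd")
  fits <- center[1] - max(radii) >= 0 && center[1] + max(radii) <= size - 1 &&
    center[2] - max(radii) >= 0 && center[2] + max(radii) <= size - 1
  tfm_abort_if(!fits, "invalid_spec", "eyelid region must fit inside the image")

  # periodic linear interpolation of the eyelid radius over angle
  ang_ext <- c(ang[1] - pi / 6 * 2, ang, ang[12] + pi / 6 * 2)
  rad_ext <- c(radii[12], radii, radii[1])
  dx <- matrix(rep(0:(size - 1), each = size), nrow = size) - center[1]   # column index - cx
  dy <- matrix(rep(0:(size - 1), times = size), nrow = size) - center[2]  # row index - cy
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  rho <- matrix(stats::approx(ang_ext, rad_ext, xout = as.vector(phi))$y,
                nrow = size)
  img <- matrix(intensities[["skin"]], size, size)
  img[d <= rho] <- intensities[["sclera"]]
  img[d <= iris_radius] <- intensities[["iris"]]
  img[d <= pupil_radius] <- intensities[["pupil"]]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmin(pmax(img + matrix(stats::rnorm(size^2, 0, noise_sd), size), 0), 255)
  }

  px <- center[1] + radii * cos(ang)
  py <- center[2] + radii * sin(ang)
  contour <- data.frame(x = px, y = py)
  # label order: upper eyelid by increasing half-circle angle, then lower
  # eyelid by decreasing half-circle angle (around-the-eye order)
  theta_half <- acos(pmin(pmax(cos(ang), -1), 1))
  lower <- sin(ang) > 0
  ord <- c(which(!lower)[order(theta_half[!lower])],
           which(lower)[order(theta_half[lower], decreasing = TRUE)])
  prefix <- if (side == "left") "L" else "R"
  points <- data.frame(label = paste0(prefix, 0:11),
                       x = px[ord], y = py[ord], stringsAsFactors = FALSE)
  Rmax <- ceiling(max(radii) + config$beta)
  truth <- data.frame(label = points$label,
                      d_true = (radii[ord] - iris_radius) / Rmax * (config$H - 1),
                      radius = radii[ord], stringsAsFactors = FALSE)
  structure(list(image = img, contour = contour, points = points,
                 truth = truth, side = side,
                 center = center, iris_radius = iris_radius,
                 pupil_radius = pupil_radius, radii = radii, Rmax = Rmax,
                 noise_sd = noise_sd, config = config),
            class = "eye_phantom")
}

#' Randomized eye phantom set
#'
#' Draws `n` phantoms with randomized iris radius, eyelid radius groups and
#' center jitter (noise-free by default), reproducibly from one seed. These
#' are the study conditions used to validate scleral distance recovery.
#'
#' @param n number of phantoms.
#' @param seed RNG seed.
#' @param size image side in pixels.
#' @param noise_sd pixel noise, default 0.
#' @param config [smue_config()] passed through to [make_eye_phantom()].
#' @return list of `eye_phantom` objects.
#' @export
random_eye_phantoms <- function(n, seed = 1L, size = 200L, noise_sd = 0,
                                config = smue_config()) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    jitter <- stats::runif(2, -6, 6)
    make_eye_phantom(
      size = size,
      center = (size - 1) / 2 + jitter,
      iris_radius = stats::runif(1, 14, 26),
      pupil_radius = 6,
      eyelid_radii = stats::runif(3, 38, 62),
      noise_sd = noise_sd,
      side = if (i %% 2 == 0) "right" else "left",
      config = config
    )
  })
}
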