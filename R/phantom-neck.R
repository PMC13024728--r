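# internal: rotate a raster about its center by `angle` radians with a
# padded canvas, bilinear resampling and constant fill; boxes follow via the
# axis-aligned hull of their transformed corners.
rotate_with_boxes <- function(image, boxes, angle, fill = 255) {
  h <- img_height(image); w <- img_width(image)
  pivot <- c((w - 1) / 2, (h - 1) / 2)
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  q <- affine_fwd(corners, 1, angle, pivot, c(0, 0))
  offset <- -c(min(q[, 1]), min(q[, 2]))
  out_w <- ceiling(max(q[, 1]) - min(q[, 1])) + 1
  out_h <- ceiling(max(q[, 2]) - min(q[, 2])) + 1
  gx <- rep(0:(out_w - 1), each = out_h)
  gy <- rep(0:(out_h - 1), times = out_w)
  ca <- cos(-angle); sa <- sin(-angle)
  px <- gx - offset[1]; py <- gy - offset[2]
  sx <- ca * px - sa * py + pivot[1]
  sy <- sa * px + ca * py + pivot[2]
  inside <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  plane <- function(m) {
    v <- bilinear_sample(m, sx, sy)
    v[!inside] <- fill
    matrix(v, nrow = out_h)
  }
  out <- if (length(dim(image)) == 2L) plane(image) else {
    array(unlist(lapply(seq_len(dim(image)[3]), function(k) plane(image[, , k]))),
          dim = c(out_h, out_w, dim(image)[3]))
  }
  # detector emulation: box centers follow the anatomy under rotation,
  # box sizes stay those of the anatomical segment
  tx <- function(b) {
    if (is.null(b)) return(NULL)
    ctr <- affine_fwd(rbind(box_center(b)), 1, angle, pivot, offset)
    hw <- (b$xmax - b$xmin) / 2; hh <- (b$ymax - b$ymin) / 2
    pixel_box(ctr[1] - hw, ctr[2] - hh, ctr[1] + hw, ctr[2] + hh)
  }
  list(image = out,
       boxes = neck_boxes(tx(boxes$top), tx(boxes$low), tx(boxes$neck)))
}

#' Synthetic neck phantom with analytic morphology metrics
#'
#' Renders a vertical skin-colored neck on a white background. The width
#' profile over normalized height `t` is a linear taper from `top_width` to
#' `bottom_width` plus an optional Gaussian bulge of peak amplitude
#' `bulge_amplitude * bottom_width`, and the whole region can be shifted
#' laterally relative to the detection-box axis (asymmetry) and rotated.
#' Top-neck and low-neck boxes are placed over the top and bottom fifths of
#' the image, centered on the unshifted axis.
#'
#' The analytic metrics are computed from the continuous width profile on
#' exactly the `S`-point row grid, ROI and midline the measurement pipeline
#' will use (same box union, margin and scale normalization), so measured
#' and analytic values are comparable number for number. The truth refers to
#' the unrotated geometry; the metrics are rotation-invariant by
#' construction up to resampling error.
#'
#' @param width,height image size in pixels.
#' @param top_width,bottom_width neck widths in pixels at the top and bottom
#'   image rows.
#' @param bulge_amplitude bulge peak as a fraction of `bottom_width`.
#' @param bulge_center,bulge_sd bulge position and spread in normalized
#'   height.
#' @param shift lateral displacement of the neck midline in pixels.
#' @param skin_rgb length-3 skin color (default inside the standard chroma
#'   box).
#' @param rotation image rotation in degrees.
#' @param noise_sd additive Gaussian pixel noise.
#' @param seed optional RNG seed applied before noise is drawn.
#' @param config an [nset_config()] supplying `Lref`, `margin`, `S` for the
#'   analytic grid.
#' @return a list of class `neck_phantom`: `image` (H x W x 3), `boxes`
#'   ([neck_boxes()]), `metrics_true` (a [neck_metrics()]), the continuous
#'   width function parameters, and the spec echo.
#' @export
make_neck_phantom <- function(width = 260L, height = 360L,
                              top_width = 100, bottom_width = 150,
                              bulge_amplitude = 0, bulge_center = 0.5,
                              bulge_sd = 0.08, shift = 0,
                              skin_rgb = c(200, 140, 110),
                              rotation = 0, noise_sd = 0, seed = NULL,
                              config = nset_config()) {
  tfm_abort_if(top_width <= 0 || bottom_width <= 0, "invalid_spec",
    "widths must be positive")
  tfm_abort_if(bulge_amplitude < 0, "invalid_spec", "bulge amplitude must be >= 0")
  w_of <- function(t) {
    top_width + (bottom_width - top_width) * t +
      bulge_amplitude * bottom_width * exp(-(t - bulge_center)^2 / (2 * bulge_sd^2))
  }
  axis_x <- (width - 1) / 2
  mid_x <- axis_x + shift
  tmax <- stats::optimize(w_of, c(0, 1), maximum = TRUE)$maximum
  max_half <- max(w_of(c(0, tmax, 1))) / 2
  tfm_abort_if(mid_x - max_half < 1 || mid_x + max_half > width - 2,
    "invalid_spec", "neck region (with shift) must fit inside the image")

  t_rows <- (0:(height - 1)) / (height - 1)
  half <- (w_of(t_rows) - 1) / 2
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  inside <- abs(xs - mid_x) <= half  # recycles half down columns
  img <- array(0, dim = c(height, width, 3L))
  for (k in 1:3) {
    plane <- matrix(255, height, width)
    plane[inside] <- skin_rgb[k]
    img[, , k] <- plane
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, noise_sd),
                                 dim = dim(img)), 0), 255)
  }

  # boxes over the upper and lower neck segments, centered on the unshifted
  # axis; placed so the margin-expanded ROI stays inside the image
  box_w <- min(width, 2 * (max_half + abs(shift)) + 8)
  boxes <- neck_boxes(
    top = pixel_box(axis_x - box_w / 2, 0.15 * (height - 1),
                    axis_x + box_w / 2, 0.30 * (height - 1)),
    low = pixel_box(axis_x - box_w / 2, 0.70 * (height - 1),
                    axis_x + box_w / 2, 0.85 * (height - 1))
  )

  metrics_true <- analytic_neck_metrics(w_of, axis_x, shift, width, height,
                                        boxes, config)

  if (rotation != 0) {
    rot <- rotate_with_boxes(img, boxes, rotation * pi / 180, fill = 255)
    img <- rot$image
    boxes <- rot$boxes
  }
  structure(list(image = img, boxes = boxes, metrics_true = metrics_true,
                 w_of = w_of, top_width = top_width,
                 bottom_width = bottom_width,
                 bulge_amplitude = bulge_amplitude, shift = shift,
                 rotation = rotation, noise_sd = noise_sd, config = config),
            class = "neck_phantom")
}

# analytic metrics on the same discrete grid, ROI and midline the pipeline
# uses: scale the boxes by s = Lref / |v|, build the ROI with neck_roi(),
# sample S rows, evaluate the continuous width there
analytic_neck_metrics <- function(w_of, axis_x, shift, width, height, boxes,
                                  config) {
  ct <- box_center(boxes$top); cl <- box_center(boxes$low)
  s <- config$Lref / sqrt(sum((cl - ct)^2))
  out_w <- ceiling(s * (width - 1)) + 1
  out_h <- ceiling(s * (height - 1)) + 1
  scale_box <- function(b) pixel_box(s * b$xmin, s * b$ymin, s * b$xmax, s * b$ymax)
  sboxes <- neck_boxes(scale_box(boxes$top), scale_box(boxes$low))
  roi <- neck_roi(sboxes, out_w, out_h, config$margin)
  hr <- roi$ymax - roi$ymin
  S <- config$S
  i <- 0:(S - 1)
  y_roi <- round_half_up(i * (hr - 1) / (S - 1))
  t_i <- pmin(pmax((roi$ymin + y_roi) / s / (height - 1), 0), 1)
  W_i <- s * w_of(t_i)
  xm_local <- (roi$xmax - roi$xmin - 1) / 2
  mid_local <- s * (axis_x + shift) - roi$xmin
  delta <- xm_local - mid_local
  neck_metrics(width_profile_from_widths(W_i,
                                         WL = W_i / 2 + delta,
                                         WR = W_i / 2 - delta))
}

#' Reference cohort of normal (zero-bulge) neck phantoms
#'
#' Generates `n` non-swollen phantoms with randomized taper, small lateral
#' jitter and mild pixel noise, reproducibly from one seed. These emulate
#' the normal reference set from which the ensemble thresholds are
#' calibrated.
#'
#' @param n cohort size (>= 2).
#' @param seed RNG seed; phantom `i` uses `seed + i` for its noise.
#' @param config an [nset_config()].
#' @return list of `neck_phantom` objects.
#' @export
make_reference_cohort <- function(n, seed = 1L, config = nset_config()) {
  tfm_abort_if(n < 2, "insufficient_cohort", "cohort needs n >= 2")
  set.seed(seed)
  params <- data.frame(
    top = stats::runif(n, 85, 115),
    bottom = stats::runif(n, 135, 170),
    shift = stats::runif(n, -3, 3)
  )
  lapply(seq_len(n), function(i) {
    make_neck_phantom(top_width = params$top[i],
                      bottom_width = params$bottom[i],
                      bulge_amplitude = 0,
                      shift = params$shift[i],
                      noise_sd = 2,
                      seed = seed + i,
                      config = config)
  })
}
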