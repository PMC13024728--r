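#' Landmark-driven periocular region extraction
#'
#' A face-mesh landmark provider (external to this package) yields normalized
#' landmark coordinates in `[0, 1]`. The eye-region extractor converts the
#' canthal anchor landmarks to pixel coordinates, pads their bounding box by a
#' fixed margin, clamps it to the image, and crops the periocular region that
#' downstream scleral measurement consumes.
#'
#' @name fmel
NULL

#' Default eye landmark configuration
#'
#' The canthal anchor indices follow the face-mesh convention: left eye
#' `c(33, 133)`, right eye `c(362, 263)`. The margin (default 50 px) pads the
#' landmark bounding box so the full eyelid contour and adjacent periocular
#' skin are retained.
#'
#' @param left_indices,right_indices integer landmark ids anchoring each eye.
#' @param margin non-negative padding in pixels.
#' @return a list of class `eye_landmark_config`.
#' @export
eye_landmark_config <- function(left_indices = c(33L, 133L),
                                right_indices = c(362L, 263L),
                                margin = 50L) {
  tfm_abort_if(length(left_indices) == 0L || length(right_indices) == 0L,
    "invalid_spec", "landmark index lists must be non-empty")
  tfm_abort_if(length(intersect(left_indices, right_indices)) > 0L,
    "invalid_spec", "left and right landmark index lists must be disjoint")
  tfm_abort_if(!is.numeric(margin) || margin < 0, "invalid_spec",
    "margin must be >= 0")
  structure(
    list(left_indices = as.integer(left_indices),
         right_indices = as.integer(right_indices),
         margin = as.numeric(margin)),
    class = "eye_landmark_config"
  )
}

#' Convert normalized landmarks to pixel coordinates
#'
#' Each normalized coordinate pair maps to `(floor(x * W), floor(y * H))` and
#' is then clamped into the valid 0-based index range, so `x = 1` lands on the
#' last column rather than one past it.
#'
#' @param landmarks data frame with columns `index`, `x`, `y` (`x`, `y`
#'   normalized to `[0, 1]`).
#' @param width,height image dimensions in pixels.
#' @return data frame with columns `index`, `x`, `y` in integer pixels.
#' @export
to_pixel_coords <- function(landmarks, width, height) {
  tfm_abort_if(is.null(landmarks) || nrow(as.data.frame(landmarks)) == 0L,
    "empty_landmarks", "landmark set is empty")
  landmarks <- as.data.frame(landmarks)
  tfm_abort_if(!all(c("index", "x", "y") %in% names(landmarks)),
    "invalid_landmark", "landmarks need columns index, x, y")
  tfm_abort_if(width < 1 || height < 1, "invalid_image",
    "width and height must be >= 1")
  bad <- landmarks$x < 0 | landmarks$x > 1 | landmarks$y < 0 | landmarks$y > 1
  tfm_abort_if(any(bad), "invalid_landmark",
    sprintf("normalized coordinates outside [0, 1] at index %s",
            paste(landmarks$index[bad], collapse = ", ")))
  data.frame(
    index = as.integer(landmarks$index),
    x = pmin(pmax(floor(landmarks$x * width), 0), width - 1),
    y = pmin(pmax(floor(landmarks$y * height), 0), height - 1)
  )
}

#' Margin-padded bounding box around landmark points
#'
#' The box is the min/max extent of the points, expanded by `margin` on every
#' side and clamped to the image: `xmin = max(0, min x - m)`,
#' `xmax = min(W, max x + m)` and analogously in y. Bounds are half-open
#' (`xmax`, `ymax` are exclusive).
#'
#' @param points data frame with pixel columns `x`, `y` (0-based).
#' @param width,height image dimensions in pixels.
#' @param margin non-negative padding in pixels.
#' @return a list of class `eye_bounding_box` with `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @export
eye_bounding_box <- function(points, width, height, margin = 50) {
  tfm_abort_if(is.null(points) || nrow(as.data.frame(points)) == 0L,
    "empty_landmarks", "point list is empty")
  tfm_abort_if(margin < 0, "invalid_spec", "margin must be >= 0")
  points <- as.data.frame(points)
  box <- list(
    xmin = max(0, min(points$x) - margin),
    xmax = min(width, max(points$x) + margin),
    ymin = max(0, min(points$y) - margin),
    ymax = min(height, max(points$y) + margin)
  )
  tfm_abort_if(box$xmin >= box$xmax || box$ymin >= box$ymax,
    "degenerate_roi", "bounding box is degenerate after clamping")
  structure(lapply(box, as.numeric), class = "eye_bounding_box")
}

#' Crop a raster to a bounding box
#'
#' Takes the half-open slice rows `[ymin, ymax)`, columns `[xmin, xmax)`; the
#' source image is left untouched.
#'
#' @param image raster (see [raster-conventions]).
#' @param box an [eye_bounding_box()] or list with `xmin`, `xmax`, `ymin`,
#'   `ymax` (0-based, half-open).
#' @param image_id optional source identifier carried along for reporting.
#' @return a list of class `eye_crop` with elements `pixels`, `box`,
#'   `image_id`.
#' @export
crop_eye <- function(image, box, image_id = "") {
  assert_raster(image)
  w <- img_width(image); h <- img_height(image)
  ok <- box$xmin >= 0 && box$ymin >= 0 && box$xmax <= w && box$ymax <= h &&
    box$xmin < box$xmax && box$ymin < box$ymax
  tfm_abort_if(!ok, "degenerate_roi", "box empty or outside the image")
  rows <- (box$ymin + 1):box$ymax
  cols <- (box$xmin + 1):box$xmax
  pixels <- if (length(dim(image)) == 2L) image[rows, cols, drop = FALSE]
            else image[rows, cols, , drop = FALSE]
  structure(list(pixels = pixels, box = box, image_id = image_id),
            class = "eye_crop")
}

#' Extract the periocular region from a face image
#'
#' Composes [to_pixel_coords()], [eye_bounding_box()] over the union of the
#' configured left- and right-eye anchor indices, and [crop_eye()]. An empty
#' landmark set is treated as a detection failure (the sample is excluded
#' upstream); a set missing a required anchor index is an input error.
#'
#' @param image face raster (see [raster-conventions]).
#' @param landmarks data frame of normalized landmarks (`index`, `x`, `y`).
#' @param config an [eye_landmark_config()].
#' @param image_id optional source identifier.
#' @return an `eye_crop` (see [crop_eye()]).
#' @export
extract_eye_region <- function(image, landmarks,
                               config = eye_landmark_config(),
                               image_id = "") {
  assert_raster(image)
  if (is.null(landmarks) || nrow(as.data.frame(landmarks)) == 0L) {
    tfm_error("detection_failure",
      "no landmarks returned for this image; sample excluded")
  }
  landmarks <- as.data.frame(landmarks)
  need <- c(config$left_indices, config$right_indices)
  missing <- setdiff(need, landmarks$index)
  tfm_abort_if(length(missing) > 0L, "missing_landmark",
    sprintf("landmark set lacks required index %s",
            paste(missing, collapse = ", ")))
  pts <- to_pixel_coords(landmarks[landmarks$index %in% need, , drop = FALSE],
                         img_width(image), img_height(image))
  box <- eye_bounding_box(pts, img_width(image), img_height(image),
                          margin = config$margin)
  crop_eye(image, box, image_id = image_id)
}

#' @export
print.eye_crop <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<eye_crop> %d x %d px", d[1], d[2]),
      if (length(d) == 3L) sprintf("x %d channels", d[3]) else "",
      sprintf(" box [%g, %g) x [%g, %g)\n",
              x$box$xmin, x$box$xmax, x$box$ymin, x$box$ymax))
  invisible(x)
}
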