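#' Raster conventions and low-level sampling
#'
#' Images are plain numeric arrays on the 8-bit scale (0--255):
#' a matrix `img[row, col]` for grayscale or an array `img[row, col, channel]`
#' with three channels for RGB. Rows run top to bottom (y), columns left to
#' right (x). All pixel coordinates in the public interface are 0-based, with
#' boxes given as half-open intervals `[min, max)`, matching the slice
#' semantics used throughout the measurement pipeline.
#'
#' @name raster-conventions
NULL

# -- validation ---------------------------------------------------------------

assert_raster <- function(img, arg = "image") {
  ok <- is.numeric(img) &&
    (length(dim(img)) == 2L || (length(dim(img)) == 3L && dim(img)[3] %in% c(1L, 3L)))
  tfm_abort_if(!ok, "invalid_image",
    sprintf("%s must be a numeric matrix or an array with 1 or 3 channels", arg))
  tfm_abort_if(any(dim(img)[1:2] < 1L), "invalid_image",
    sprintf("%s must have positive dimensions", arg))
  invisible(img)
}

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]
img_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3] else 1L

#' Convert a raster to grayscale
#'
#' Three-channel rasters are reduced with the standard luma weights
#' (0.299, 0.587, 0.114); grayscale input is returned unchanged.
#'
#' @param img numeric matrix or H x W x 3 array on the 0--255 scale.
#' @return numeric matrix (H x W).
#' @export
as_gray <- function(img) {
  assert_raster(img)
  if (length(dim(img)) == 2L) return(img)
  if (dim(img)[3] == 1L) return(img[, , 1L])
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Round half away from zero (for non-negative pixel arithmetic this is
# round-half-up). base::round() rounds halves to even, which would make
# sampled row indices depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# -- bilinear sampling with edge clamping -------------------------------------

#' Sample a grayscale raster at sub-pixel positions
#'
#' Bilinear interpolation at 0-based coordinates `(x, y)`; positions outside
#' the raster are clamped to the nearest edge pixel, so the sampler is total.
#'
#' @param img numeric matrix (grayscale raster).
#' @param x,y numeric vectors of equal length, 0-based column/row positions.
#' @return numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(img, x, y) {
  assert_raster(img)
  tfm_abort_if(length(dim(img)) != 2L, "invalid_image",
    "bilinear_sample expects a grayscale matrix; convert with as_gray()")
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  # 1-based indexing into the matrix via linear indices
  idx <- function(r, c) r + 1 + c * h
  v00 <- img[idx(y0, x0)]; v01 <- img[idx(y0, x1)]
  v10 <- img[idx(y1, x0)]; v11 <- img[idx(y1, x1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# -- colour space -------------------------------------------------------------

# Full-range BT.601 YCrCb, the convention used by mainstream image libraries.
rgb_to_ycrcb <- function(img) {
  assert_raster(img)
  tfm_abort_if(img_channels(img) != 3L, "invalid_image",
    "rgb_to_ycrcb expects a 3-channel raster")
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cr <- (r - y) * 0.713 + 128
  cb <- (b - y) * 0.564 + 128
  out <- array(0, dim = dim(img))
  out[, , 1L] <- y; out[, , 2L] <- cr; out[, , 3L] <- cb
  out
}

# -- EBImage bridge -----------------------------------------------------------

# EBImage stores images as [x, y(, channel)] in [0, 1]; this package uses
# [row, col] matrices in [0, 255]. The bridge keeps that conversion in one
# place.
to_ebimage <- function(img) {
  assert_raster(img)
  if (length(dim(img)) == 2L) {
    EBImage::Image(t(img) / 255)
  } else {
    EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
  }
}

from_ebimage <- function(x) {
  d <- EBImage::imageData(x)
  if (length(dim(d)) == 2L) {
    t(d) * 255
  } else {
    aperm(d, c(2L, 1L, 3L)) * 255
  }
}

#' Read an image file as an 8-bit raster
#'
#' PNG, JPEG and TIFF are supported. Color images come back as H x W x 3
#' arrays, grayscale as matrices, always on the 0--255 scale.
#'
#' @param path file path.
#' @return numeric matrix or array (see [raster-conventions]).
#' @export
read_raster <- function(path) {
  tfm_abort_if(!file.exists(path), "parse_error", sprintf("file not found: %s", path))
  x <- EBImage::readImage(path)
  d <- EBImage::imageData(x)
  if (length(dim(d)) == 3L && dim(d)[3] > 3L) d <- d[, , 1:3]  # drop alpha
  if (length(dim(d)) == 3L && dim(d)[3] == 2L) d <- d[, , 1L]  # gray+alpha
  if (length(dim(d)) == 2L) t(d) * 255 else aperm(d, c(2L, 1L, 3L)) * 255
}

#' Write an 8-bit raster to a PNG file
#'
#' @param img raster (see [raster-conventions]).
#' @param path output path; the format is taken from the file extension.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  assert_raster(img)
  x <- to_ebimage(pmin(pmax(img, 0), 255))
  EBImage::writeImage(x, path)
  invisible(path)
}
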