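#' Neck analysis configuration
#'
#' Collects the tunable constants of the neck pipeline. Defaults follow the
#' method's stated operating point (`k = 2`, `q = 2`, `S = 60`,
#' `margin = 0.10`); the reference axis length, skin-color box and
#' enhancement/morphology settings are implementation choices documented in
#' the methods vignette.
#'
#' @param Lref target length in pixels of the top-to-low neck axis after
#'   alignment (scale normalization). Default 200.
#' @param margin fractional expansion of the union ROI on each side.
#' @param S number of equally spaced rows sampled from the width profile.
#' @param k threshold multiplier (`theta = mu + k * sigma`).
#' @param q vote quorum: flag Swollen when at least `q` of the four metrics
#'   exceed their thresholds.
#' @param mode `"vertical"` rotates the top-to-low axis onto +y so width is
#'   measured across image rows; `"literal"` rotates by `-phi`, aligning the
#'   axis with +x.
#' @param fill intensity used for pixels that fall outside the source image
#'   after alignment (default 255, a non-skin white).
#' @param clahe,skin,morph see [clahe_spec()], [skin_spec()], [morph_spec()].
#' @return a list of class `nset_config`.
#' @export
nset_config <- function(Lref = 200, margin = 0.10, S = 60L, k = 2, q = 2L,
                        mode = c("vertical", "literal"), fill = 255,
                        clahe = clahe_spec(), skin = skin_spec(),
                        morph = morph_spec()) {
  mode <- match.arg(mode)
  tfm_abort_if(Lref <= 0, "invalid_spec", "Lref must be positive")
  tfm_abort_if(margin < 0, "invalid_spec", "margin must be >= 0")
  tfm_abort_if(S < 4, "invalid_spec", "S must be >= 4")
  tfm_abort_if(k < 0, "invalid_spec", "k must be >= 0")
  tfm_abort_if(q < 1 || q > 4, "invalid_spec", "q must be in 1..4")
  structure(list(Lref = Lref, margin = margin, S = as.integer(S), k = k,
                 q = as.integer(q), mode = mode, fill = fill,
                 clahe = clahe, skin = skin, morph = morph),
            class = "nset_config")
}

#' @rdname nset_config
#' @param clip_limit CLAHE contrast clip limit.
#' @param tiles CLAHE tile grid size per axis.
#' @export
clahe_spec <- function(clip_limit = 2, tiles = 8L) {
  structure(list(clip_limit = clip_limit, tiles = as.integer(tiles)),
            class = "clahe_spec")
}

#' @rdname nset_config
#' @param space `"ycrcb"` (chroma box on Cr/Cb) or `"gray"` (luminance band,
#'   the fallback for single-channel images).
#' @param cr,cb inclusive chroma ranges for skin in YCrCb.
#' @param gray inclusive luminance range for skin in grayscale mode.
#' @export
skin_spec <- function(space = c("ycrcb", "gray"),
                      cr = c(133, 173), cb = c(77, 127),
                      gray = c(40, 245)) {
  space <- match.arg(space)
  structure(list(space = space, cr = cr, cb = cb, gray = gray),
            class = "skin_spec")
}

#' @rdname nset_config
#' @param size diameter in pixels of the elliptical structuring element
#'   (odd).
#' @export
morph_spec <- function(size = 5L) {
  tfm_abort_if(size %% 2 != 1, "invalid_spec", "structuring element size must be odd")
  structure(list(size = as.integer(size)), class = "morph_spec")
}

# -- boxes --------------------------------------------------------------------

#' Pixel box and neck box pair constructors
#'
#' Boxes are 0-based and half-open: `[xmin, xmax) x [ymin, ymax)`. A
#' `neck_boxes` object holds the top-neck and low-neck detection boxes (an
#' optional whole-neck box is accepted and carried along, but the
#' computation never uses it).
#'
#' @param xmin,ymin,xmax,ymax box bounds in pixels.
#' @return `pixel_box`: a classed list of the four bounds.
#' @export
pixel_box <- function(xmin, ymin, xmax, ymax) {
  tfm_abort_if(xmin >= xmax || ymin >= ymax, "degenerate_roi",
    "pixel box must have positive extent")
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "pixel_box")
}

box_center <- function(box) {
  c(x = (box$xmin + box$xmax) / 2, y = (box$ymin + box$ymax) / 2)
}

#' @rdname pixel_box
#' @param top,low,neck [pixel_box()]es for the top-neck and low-neck regions
#'   and optionally the whole neck.
#' @export
neck_boxes <- function(top, low, neck = NULL) {
  ct <- box_center(top); cl <- box_center(low)
  tfm_abort_if(all(ct == cl), "degenerate_axis",
    "top and low box centers coincide")
  structure(list(top = top, low = low, neck = neck), class = "neck_boxes")
}

# -- alignment ----------------------------------------------------------------

# forward affine p' = s * R(angle) * (p - pivot) + offset, applied to an
# n x 2 matrix of (x, y) coordinates
affine_fwd <- function(p, s, angle, pivot, offset) {
  ca <- cos(angle); sa <- sin(angle)
  px <- p[, 1] - pivot[1]; py <- p[, 2] - pivot[2]
  cbind(s * (ca * px - sa * py) + offset[1],
        s * (sa * px + ca * py) + offset[2])
}

#' Align a neck image on its top-to-low axis
#'
#' The vector `v` from the top-neck box center to the low-neck box center
#' defines the neck axis (`phi = atan2(vy, vx)`). The image is rotated about
#' the midpoint of the two centers so the axis points straight down (+y;
#' `mode = "literal"` instead rotates by `-phi`, putting the axis on +x),
#' then scaled by `s = Lref / |v|`, with bilinear resampling onto a canvas
#' padded so no content is lost. Boxes are carried through the same
#' transform (corners mapped, then the axis-aligned hull taken).
#'
#' @param image raster (see [raster-conventions]).
#' @param boxes a [neck_boxes()].
#' @param config an [nset_config()] (uses `Lref`, `mode`, `fill`).
#' @return a list of class `neck_alignment`: aligned `image`, transformed
#'   `boxes`, scale `s`, axis angle `phi`, applied rotation `angle`, and the
#'   transform parameters (`pivot`, `offset`).
#' @export
align_neck <- function(image, boxes, config = nset_config()) {
  assert_raster(image)
  ct <- unname(box_center(boxes$top)); cl <- unname(box_center(boxes$low))
  v <- cl - ct
  nv <- sqrt(sum(v^2))
  tfm_abort_if(nv == 0, "degenerate_axis", "top and low box centers coincide")
  phi <- atan2(v[2], v[1])
  angle <- if (config$mode == "vertical") pi / 2 - phi else -phi
  s <- config$Lref / nv
  pivot <- (ct + cl) / 2
  h <- img_height(image); w <- img_width(image)
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  q <- affine_fwd(corners, s, angle, pivot, c(0, 0))
  offset <- -c(min(q[, 1]), min(q[, 2]))
  out_w <- ceiling(max(q[, 1]) - min(q[, 1])) + 1
  out_h <- ceiling(max(q[, 2]) - min(q[, 2])) + 1

  # inverse map output pixel centers into the source image
  gx <- rep(0:(out_w - 1), each = out_h)
  gy <- rep(0:(out_h - 1), times = out_w)
  ca <- cos(-angle); sa <- sin(-angle)
  px <- (gx - offset[1]) / s; py <- (gy - offset[2]) / s
  sx <- ca * px - sa * py + pivot[1]
  sy <- sa * px + ca * py + pivot[2]
  inside <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  sample_plane <- function(m) {
    vals <- bilinear_sample(m, sx, sy)
    vals[!inside] <- config$fill
    matrix(vals, nrow = out_h)
  }
  aligned <- if (length(dim(image)) == 2L) {
    sample_plane(image)
  } else {
    planes <- lapply(seq_len(dim(image)[3]), function(k) sample_plane(image[, , k]))
    array(unlist(planes), dim = c(out_h, out_w, dim(image)[3]))
  }

  # boxes describe anatomical segments: their centers follow the affine
  # exactly, their extents are scale-only (no axis-aligned-hull inflation,
  # which would make the ROI depend on the incidental camera rotation)
  tx_box <- function(box) {
    if (is.null(box)) return(NULL)
    ctr <- affine_fwd(rbind(box_center(box)), s, angle, pivot, offset)
    hw <- s * (box$xmax - box$xmin) / 2
    hh <- s * (box$ymax - box$ymin) / 2
    pixel_box(max(0, ctr[1] - hw), max(0, ctr[2] - hh),
              min(out_w, ctr[1] + hw), min(out_h, ctr[2] + hh))
  }
  structure(list(
    image = aligned,
    boxes = neck_boxes(tx_box(boxes$top), tx_box(boxes$low), tx_box(boxes$neck)),
    s = s, phi = phi, angle = angle, Lref = config$Lref,
    pivot = pivot, offset = offset
  ), class = "neck_alignment")
}

#' Region of interest around the neck boxes
#'
#' Union of the top and low boxes, expanded on each side by `margin_frac`
#' of the union's own width (in x) and height (in y), clamped to the image
#' and snapped to whole pixels (floor on the lower bounds, ceiling on the
#' upper).
#'
#' @param boxes a [neck_boxes()] (in aligned coordinates).
#' @param width,height dimensions of the image the ROI must stay within.
#' @param margin_frac fractional margin, default 0.10.
#' @return a [pixel_box()].
#' @export
neck_roi <- function(boxes, width, height, margin_frac = 0.10) {
  tfm_abort_if(margin_frac < 0, "invalid_spec", "margin_frac must be >= 0")
  xmin <- min(boxes$top$xmin, boxes$low$xmin)
  xmax <- max(boxes$top$xmax, boxes$low$xmax)
  ymin <- min(boxes$top$ymin, boxes$low$ymin)
  ymax <- max(boxes$top$ymax, boxes$low$ymax)
  mw <- margin_frac * (xmax - xmin)
  mh <- margin_frac * (ymax - ymin)
  pixel_box(floor(max(0, xmin - mw)), floor(max(0, ymin - mh)),
            ceiling(min(width, xmax + mw)), ceiling(min(height, ymax + mh)))
}

# -- enhancement and skin mask ------------------------------------------------

apply_clahe <- function(gray, spec) {
  h <- nrow(gray); w <- ncol(gray)
  if (diff(range(gray)) == 0) return(gray)  # equalizing a constant is a no-op
  nx <- max(1L, min(spec$tiles, w %/% 8L))
  ny <- max(1L, min(spec$tiles, h %/% 8L))
  # the equalizer needs dimensions divisible by the tile counts: replicate
  # the last row/column out to the next multiple, then crop back
  wp <- ceiling(w / nx) * nx
  hp <- ceiling(h / ny) * ny
  padded <- gray[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
                 drop = FALSE]
  eb <- EBImage::clahe(to_ebimage(padded), nx = nx, ny = ny,
                       limit = spec$clip_limit, keep.range = TRUE)
  out <- from_ebimage(eb)[seq_len(h), seq_len(w), drop = FALSE]
  pmin(pmax(out, 0), 255)
}

#' Contrast-normalize a neck ROI and extract its skin mask
#'
#' The luminance channel is equalized with CLAHE; skin pixels are selected
#' by a chroma box in YCrCb (or a luminance band for grayscale input); the
#' binary mask is cleaned by morphological opening then closing with an
#' elliptical structuring element, and only the largest connected component
#' is kept.
#'
#' @param roi_image raster of the cropped ROI.
#' @param config an [nset_config()] (uses `clahe`, `skin`, `morph`).
#' @return a list of class `neck_mask`: binary `mask` (0/1 integer matrix),
#'   `enhanced` raster, and the specs used.
#' @export
enhance_and_mask <- function(roi_image, config = nset_config()) {
  assert_raster(roi_image)
  skin <- config$skin
  if (img_channels(roi_image) == 3L && skin$space == "ycrcb") {
    ycc <- rgb_to_ycrcb(roi_image)
    yl <- apply_clahe(ycc[, , 1L], config$clahe)
    enhanced <- ycc; enhanced[, , 1L] <- yl
    cr <- enhanced[, , 2L]; cb <- enhanced[, , 3L]
    raw <- (cr >= skin$cr[1] & cr <= skin$cr[2] &
            cb >= skin$cb[1] & cb <= skin$cb[2]) * 1L
  } else {
    gray <- as_gray(roi_image)
    enhanced <- apply_clahe(gray, config$clahe)
    raw <- (enhanced >= skin$gray[1] & enhanced <= skin$gray[2]) * 1L
  }
  dim(raw) <- dim(roi_image)[1:2]
  brush <- EBImage::makeBrush(config$morph$size, shape = "disc")
  m <- EBImage::closing(EBImage::opening(raw, brush), brush)
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) {
    tfm_error("no_skin_detected", "no skin-range pixels survive post-processing")
  }
  counts <- tabulate(lab[lab > 0])
  mask <- (lab == which.max(counts)) * 1L
  dim(mask) <- dim(raw)
  structure(list(mask = mask, enhanced = enhanced,
                 clahe = config$clahe, skin = skin, morph = config$morph),
            class = "neck_mask")
}

# -- width profile ------------------------------------------------------------

#' Width profile of a binary neck mask
#'
#' Samples `S` rows at `y_i = round(i * (h - 1) / (S - 1))`. On each row with
#' mask pixels, the width is `x_R - x_L + 1` between the outermost mask
#' columns; the side widths split the total about the fixed ROI midline
#' `x_m = (mask width - 1) / 2`. Band means `Wtop` (rows 10--20% down) and
#' `Wbot` (80--90%) use `round(frac * (S - 1))` index bounds and skip invalid
#' rows; `Wbot` is guarded to at least 1. The linear baseline `Wlin`
#' interpolates the widths of the first and last valid sampled rows, and
#' `dev = max(W - Wlin, 0)` is the positive bulge deviation.
#'
#' @param mask a [enhance_and_mask()] result or a 0/1 matrix.
#' @param S number of sampled rows (>= 4), default 60.
#' @return a list of class `width_profile`: per-row data frame `rows`
#'   (`i`, `y`, `xL`, `xR`, `W`, `WL`, `WR`, `valid`), the band means
#'   `Wtop`, `Wbot`, baseline `Wlin`, deviations `dev`, midline `xm` and `S`.
#' @export
width_profile <- function(mask, S = 60L) {
  if (inherits(mask, "neck_mask")) mask <- mask$mask
  tfm_abort_if(S < 4, "invalid_spec", "S must be >= 4")
  tfm_abort_if(sum(mask) == 0, "no_skin_detected", "mask is empty")
  h <- nrow(mask); w <- ncol(mask)
  xm <- (w - 1) / 2
  i <- 0:(S - 1)
  y <- round_half_up(i * (h - 1) / (S - 1))
  xL <- xR <- W <- WL <- WR <- rep(NA_real_, S)
  for (k in seq_len(S)) {
    cols <- which(mask[y[k] + 1, ] == 1L)
    if (length(cols) == 0L) next
    xL[k] <- cols[1] - 1
    xR[k] <- cols[length(cols)] - 1
    W[k] <- xR[k] - xL[k] + 1
    WL[k] <- xm - xL[k]
    WR[k] <- xR[k] - xm
  }
  valid <- !is.na(W)
  profile_from_sampled(i, y, xL, xR, W, WL, WR, valid, xm, S)
}

# shared grid arithmetic for measured and analytic profiles
profile_from_sampled <- function(i, y, xL, xR, W, WL, WR, valid, xm, S) {
  band <- function(fa, fb) {
    idx <- round_half_up(fa * (S - 1)):round_half_up(fb * (S - 1))
    sel <- idx[valid[idx + 1]]
    tfm_abort_if(length(sel) == 0L, "insufficient_profile",
      sprintf("no valid rows in the %.0f-%.0f%% band", fa * 100, fb * 100))
    mean(W[sel + 1])
  }
  Wtop <- band(0.10, 0.20)
  Wbot <- band(0.80, 0.90)
  if (Wbot <= 0) Wbot <- 1
  vi <- which(valid)
  i_first <- vi[1]; i_last <- vi[length(vi)]
  Wlin <- rep(NA_real_, S)
  if (i_last == i_first) {
    Wlin[vi] <- W[i_first]
  } else {
    frac <- (i - i[i_first]) / (i[i_last] - i[i_first])
    Wlin <- W[i_first] + (W[i_last] - W[i_first]) * frac
    Wlin[!valid] <- NA_real_
  }
  dev <- pmax(W - Wlin, 0)
  structure(list(
    rows = data.frame(i = i, y = y, xL = xL, xR = xR, W = W,
                      WL = WL, WR = WR, valid = valid),
    Wtop = Wtop, Wbot = Wbot, Wlin = Wlin, dev = dev, xm = xm, S = S
  ), class = "width_profile")
}

#' Width profile from known per-row widths
#'
#' Builds a `width_profile` directly from numeric widths on the `S`-point
#' grid, bypassing any image. This is the entry point for analytic ground
#' truth (phantoms) and for checking the band/baseline arithmetic against
#' hand-computed values. Side widths default to a symmetric split.
#'
#' @param W numeric vector of widths (`NA` marks invalid rows).
#' @param WL,WR optional side widths; default `W / 2` each.
#' @return a `width_profile` (see [width_profile()]).
#' @export
width_profile_from_widths <- function(W, WL = W / 2, WR = W / 2) {
  S <- length(W)
  tfm_abort_if(S < 4, "invalid_spec", "need at least 4 rows")
  valid <- !is.na(W)
  tfm_abort_if(!any(valid), "no_skin_detected", "all rows invalid")
  i <- 0:(S - 1)
  profile_from_sampled(i, i, NA_real_, NA_real_, W, WL, WR, valid,
                       xm = NA_real_, S = S)
}

#' Neck morphology metrics
#'
#' Four unitless indices over a [width_profile()]:
#' `TLR = Wtop / Wbot` (top-to-low width ratio),
#' `BPI = max(dev) / Wbot` (bulge peak index),
#' `BAR = mean(dev) / Wbot` (bulge area ratio), and
#' `ASR = sum |WL - WR| / sum (WL + WR)` (asymmetry ratio), with all sums and
#' means over valid rows only.
#'
#' @param profile a [width_profile()].
#' @return a list of class `neck_metrics` with `TLR`, `BPI`, `BAR`, `ASR`.
#' @export
neck_metrics <- function(profile) {
  valid <- profile$rows$valid
  dev <- profile$dev[valid]
  WL <- profile$rows$WL[valid]; WR <- profile$rows$WR[valid]
  structure(list(
    TLR = profile$Wtop / profile$Wbot,
    BPI = max(dev) / profile$Wbot,
    BAR = mean(dev) / profile$Wbot,
    ASR = sum(abs(WL - WR)) / sum(WL + WR)
  ), class = "neck_metrics")
}

#' @export
print.neck_metrics <- function(x, ...) {
  cat(sprintf("<neck_metrics> TLR %.4f  BPI %.4f  BAR %.4f  ASR %.4f\n",
              x$TLR, x$BPI, x$BAR, x$ASR))
  invisible(x)
}

#' @export
as.data.frame.neck_metrics <- function(x, ...) {
  data.frame(TLR = x$TLR, BPI = x$BPI, BAR = x$BAR, ASR = x$ASR)
}
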