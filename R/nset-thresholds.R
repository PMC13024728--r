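#' Calibrate mean + k*sd ensemble thresholds on a normal cohort
#'
#' For each morphology metric (TLR, BPI, BAR, ASR) measured on a cohort of
#' non-swollen necks, the sample mean `mu` and sample standard deviation
#' `sigma` (denominator `n - 1`) define the decision threshold
#' `theta = mu + k * sigma`. Values notably above the normal mean relative
#' to its natural variability then count as atypical. Thresholds should be
#' recalibrated whenever imaging conditions or the reference population
#' change.
#'
#' @param normal_metrics a list of [neck_metrics()] or a data frame with
#'   columns `TLR`, `BPI`, `BAR`, `ASR`, one row per cohort image.
#' @param k threshold multiplier, default 2.
#' @return an object of class `nset_thresholds`: data frame `metrics`
#'   (`metric`, `mu`, `sigma`, `theta`), plus `k`, `n` and `ddof`.
#' @export
nset_calibrate <- function(normal_metrics, k = 2) {
  if (is.list(normal_metrics) && !is.data.frame(normal_metrics)) {
    normal_metrics <- do.call(rbind, lapply(normal_metrics, as.data.frame))
  }
  normal_metrics <- as.data.frame(normal_metrics)
  tfm_abort_if(nrow(normal_metrics) < 2L, "insufficient_cohort",
    "threshold calibration needs a cohort of at least 2")
  nm <- c("TLR", "BPI", "BAR", "ASR")
  tfm_abort_if(!all(nm %in% names(normal_metrics)), "invalid_spec",
    "cohort metrics need columns TLR, BPI, BAR, ASR")
  mu <- vapply(normal_metrics[nm], mean, numeric(1))
  sigma <- vapply(normal_metrics[nm], stats::sd, numeric(1))
  structure(list(
    metrics = data.frame(metric = nm, mu = unname(mu), sigma = unname(sigma),
                         theta = unname(mu + k * sigma)),
    k = k, n = nrow(normal_metrics), ddof = 1L
  ), class = "nset_thresholds")
}

#' @export
print.nset_thresholds <- function(x, ...) {
  cat(sprintf("<nset_thresholds> calibrated on n = %d normals, k = %g (theta = mu + k*sigma)\n",
              x$n, x$k))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.nset_thresholds <- function(object, ...) print(object, ...)

#' Vote a neck Swollen or Normal against calibrated thresholds
#'
#' Each metric casts a vote when it strictly exceeds its threshold; the
#' verdict is Swollen when at least `q` of the four votes are cast. A metric
#' exactly equal to its threshold does not vote.
#'
#' @param metrics a [neck_metrics()].
#' @param thresholds an [nset_calibrate()] result.
#' @param q vote quorum, default 2.
#' @return a list of class `nset_decision`: named `votes` (0/1), `score`,
#'   `q`, `result` (`"Swollen"` or `"Normal"`) and the metric values.
#' @export
nset_decide <- function(metrics, thresholds, q = 2L) {
  tfm_abort_if(!inherits(thresholds, "nset_thresholds"), "invalid_spec",
    "thresholds must come from nset_calibrate()")
  tab <- thresholds$metrics
  tfm_abort_if(!all(c("TLR", "BPI", "BAR", "ASR") %in% tab$metric),
    "invalid_spec", "thresholds must cover all four metrics")
  vals <- c(TLR = metrics$TLR, BPI = metrics$BPI,
            BAR = metrics$BAR, ASR = metrics$ASR)
  theta <- stats::setNames(tab$theta, tab$metric)[names(vals)]
  votes <- as.integer(vals > theta)
  names(votes) <- names(vals)
  score <- sum(votes)
  structure(list(votes = votes, score = score, q = as.integer(q),
                 result = if (score >= q) "Swollen" else "Normal",
                 metrics = vals, theta = theta),
            class = "nset_decision")
}

#' @export
print.nset_decision <- function(x, ...) {
  cat(sprintf("<nset_decision> %s (score %d of quorum %d)\n",
              x$result, x$score, x$q))
  tab <- data.frame(metric = names(x$metrics), value = unname(x$metrics),
                    theta = unname(x$theta), vote = unname(x$votes))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, tfm_error = function(e) {
    e$message <- sprintf("[%s] %s", stage, e$message)
    stop(e)
  })
}

#' Run the full neck pipeline on one image
#'
#' Composes [align_neck()], [neck_roi()], [enhance_and_mask()],
#' [width_profile()], [neck_metrics()] and [nset_decide()]; deterministic
#' for fixed inputs. Stage failures propagate with the stage name prefixed
#' to the message.
#'
#' @param image neck raster.
#' @param boxes a [neck_boxes()] in source-image coordinates.
#' @param thresholds an [nset_calibrate()] result, or `NULL` to stop after
#'   the metrics.
#' @param config an [nset_config()].
#' @return a list of class `nset_result`: `decision` (or `NULL`), `metrics`,
#'   `profile`, `mask`, `roi`, `alignment`.
#' @export
run_nset <- function(image, boxes, thresholds = NULL,
                     config = nset_config()) {
  alignment <- with_stage("align_neck", align_neck(image, boxes, config))
  roi <- with_stage("neck_roi",
    neck_roi(alignment$boxes, img_width(alignment$image),
             img_height(alignment$image), config$margin))
  roi_img <- with_stage("crop_roi", crop_eye(alignment$image, roi)$pixels)
  mask <- with_stage("enhance_and_mask", enhance_and_mask(roi_img, config))
  profile <- with_stage("width_profile", width_profile(mask, config$S))
  metrics <- with_stage("neck_metrics", neck_metrics(profile))
  decision <- if (!is.null(thresholds)) {
    with_stage("nset_decide", nset_decide(metrics, thresholds, config$q))
  }
  structure(list(decision = decision, metrics = metrics, profile = profile,
                 mask = mask, roi = roi, alignment = alignment),
            class = "nset_result")
}

#' @export
print.nset_result <- function(x, ...) {
  print(x$metrics)
  if (!is.null(x$decision)) print(x$decision)
  invisible(x)
}

#' Predict method for calibrated thresholds
#'
#' Applies the fitted mean + k*sd thresholds to new data: either
#' already-computed [neck_metrics()] or a raw image plus boxes (in which case
#' the full [run_nset()] pipeline runs first).
#'
#' @param object an `nset_thresholds` model.
#' @param newdata a `neck_metrics` object, or a list with elements `image`
#'   and `boxes`.
#' @param q vote quorum, default 2.
#' @param config an [nset_config()] used when `newdata` is an image.
#' @param ... unused.
#' @return an `nset_decision`.
#' @export
predict.nset_thresholds <- function(object, newdata, q = 2L,
                                    config = nset_config(), ...) {
  if (inherits(newdata, "neck_metrics")) {
    return(nset_decide(newdata, object, q))
  }
  if (is.list(newdata) && !is.null(newdata$image) && !is.null(newdata$boxes)) {
    res <- run_nset(newdata$image, newdata$boxes, object, config)
    return(res$decision)
  }
  tfm_error("invalid_spec",
    "newdata must be neck_metrics or a list with image and boxes")
}
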