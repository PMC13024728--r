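#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (= sensitivity) and specificity from the four
#' confusion counts. A metric whose denominator is zero is undefined and
#' reported as `NA` rather than coerced to 0 or 1.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named list with `accuracy`, `precision`, `recall`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  tfm_abort_if(any(counts < 0) || any(counts != round(counts)),
    "invalid_spec", "confusion counts must be non-negative integers")
  tfm_abort_if(sum(counts) == 0, "undefined_metric", "all counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- ratio(tp, tp + fn)
  list(
    accuracy = ratio(tp + tn, tp + fn + tn + fp),
    precision = ratio(tp, tp + fp),
    recall = recall,
    sensitivity = recall,
    specificity = ratio(tn, tn + fp)
  )
}

#' Areas under the ROC and precision-recall curves
#'
#' AUROC is the trapezoidal area under the empirical ROC curve, with tied
#' scores collapsed into single curve segments (equivalent to the
#' Mann-Whitney statistic with half-credit for ties). AUPRC uses the
#' step-wise precision envelope: at each recall level, the maximum
#' precision attained at that recall or higher.
#'
#' @param scores numeric confidences, higher = more positive.
#' @param labels binary ground truth (0/1 or logical), same length.
#' @return list with `AUROC` and `AUPRC`.
#' @export
roc_pr_areas <- function(scores, labels) {
  labels <- as.integer(labels)
  tfm_abort_if(length(scores) != length(labels), "invalid_spec",
    "scores and labels must have equal length")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  tfm_abort_if(P == 0L || N == 0L, "undefined_metric",
    "AUROC/AUPRC need both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single operating points
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(l, grp, sum)
  n_g <- tapply(l, grp, length)
  tp <- cumsum(tp_g); fp <- cumsum(n_g - tp_g)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  # precision envelope: non-increasing from the right
  env <- rev(cummax(rev(precision)))
  auprc <- sum(diff(c(0, recall)) * env)
  list(AUROC = auroc, AUPRC = auprc)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

average_precision <- function(det, gt, iou_threshold, interpolation) {
  n_gt <- nrow(gt)
  if (nrow(det) == 0L) return(0)
  det <- det[order(-det$score), , drop = FALSE]
  matched <- rep(FALSE, n_gt)
  tp <- numeric(nrow(det))
  for (d in seq_len(nrow(det))) {
    ious <- vapply(seq_len(n_gt), function(g) {
      box_iou(as.numeric(det[d, c("xmin", "ymin", "xmax", "ymax")]),
              as.numeric(gt[g, c("xmin", "ymin", "xmax", "ymax")]))
    }, numeric(1))
    same_img <- gt$image == det$image[d]
    cand <- which(!matched & same_img & ious >= iou_threshold)
    if (length(cand) > 0L) {
      # highest IoU wins; first ground truth on ties
      best <- cand[which.max(ious[cand])]
      matched[best] <- TRUE
      tp[d] <- 1
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  if (interpolation == "all") {
    env <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r - 1e-12]
      if (length(p) == 0L) 0 else max(p)
    }, numeric(1)))
  }
}

#' Mean average precision over detection classes
#'
#' Detections are matched to ground truth greedily in decreasing confidence
#' order within each class (and image); a detection is a true positive when
#' its IoU with an unmatched ground-truth box reaches the threshold
#' (default 0.5). Per-class AP integrates the precision envelope over recall
#' (all-point interpolation; an 11-point variant is available); mAP averages
#' AP over the classes that have ground truth.
#'
#' @param detections data frame with columns `class`, `score`, `xmin`,
#'   `ymin`, `xmax`, `ymax` and optionally `image`.
#' @param truths data frame with columns `class`, `xmin`, `ymin`, `xmax`,
#'   `ymax` and optionally `image`.
#' @param iou_threshold IoU needed for a match, in (0, 1]; default 0.5.
#' @param interpolation `"all"` (continuous) or `"11point"`.
#' @return list with `mAP` and the per-class `AP` (named).
#' @export
mean_average_precision <- function(detections, truths, iou_threshold = 0.5,
                                   interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  tfm_abort_if(iou_threshold <= 0 || iou_threshold > 1, "invalid_spec",
    "iou_threshold must be in (0, 1]")
  detections <- as.data.frame(detections)
  truths <- as.data.frame(truths)
  tfm_abort_if(nrow(truths) == 0L, "undefined_metric",
    "no ground truth in any class")
  if (is.null(detections$image)) detections$image <- "img"
  if (is.null(truths$image)) truths$image <- "img"
  classes <- sort(unique(truths$class))
  ap <- vapply(classes, function(cl) {
    average_precision(detections[detections$class == cl, , drop = FALSE],
                      truths[truths$class == cl, , drop = FALSE],
                      iou_threshold, interpolation)
  }, numeric(1))
  names(ap) <- as.character(classes)
  list(mAP = mean(ap), AP = ap)
}
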