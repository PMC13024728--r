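#' Read detection boxes from a YOLO label file
#'
#' Each row is `class cx cy w h` with center and size normalized to the
#' image; boxes are denormalized into 0-based pixel coordinates. The class
#' map assigns YOLO integer classes to the roles `neck` (optional), `top`
#' and `low`.
#'
#' @param path label file path.
#' @param width,height image size in pixels.
#' @param class_map named integer vector mapping roles to YOLO class ids.
#' @return a [neck_boxes()].
#' @export
read_yolo_labels <- function(path, width, height,
                             class_map = c(neck = 0L, top = 1L, low = 2L)) {
  tfm_abort_if(!file.exists(path), "parse_error",
    sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tfm_abort_if(length(lines) == 0L, "missing_box",
    sprintf("no boxes in %s", path))
  found <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5L || any(is.na(vals))) {
      tfm_error("parse_error",
        sprintf("%s line %d: expected 'class cx cy w h', got '%s'",
                path, ln, lines[ln]))
    }
    role <- names(class_map)[match(vals[1], class_map)]
    if (is.na(role)) {
      tfm_error("parse_error",
        sprintf("%s line %d: class %g not in class map", path, ln, vals[1]))
    }
    cx <- vals[2] * width; cy <- vals[3] * height
    bw <- vals[4] * width; bh <- vals[5] * height
    found[[role]] <- pixel_box(cx - bw / 2, cy - bh / 2,
                               cx + bw / 2, cy + bh / 2)
  }
  missing <- setdiff(c("top", "low"), names(found))
  tfm_abort_if(length(missing) > 0L, "missing_box",
    sprintf("%s: missing required class(es) %s", path,
            paste(missing, collapse = ", ")))
  neck_boxes(top = found$top, low = found$low, neck = found$neck)
}

#' Write detection boxes as a YOLO label file
#'
#' @param boxes a [neck_boxes()].
#' @param path output path.
#' @param width,height image size for normalization.
#' @inheritParams read_yolo_labels
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path, width, height,
                              class_map = c(neck = 0L, top = 1L, low = 2L)) {
  fmt <- function(role, box) {
    sprintf("%d %.10g %.10g %.10g %.10g", class_map[[role]],
            (box$xmin + box$xmax) / 2 / width,
            (box$ymin + box$ymax) / 2 / height,
            (box$xmax - box$xmin) / width,
            (box$ymax - box$ymin) / height)
  }
  out <- c(if (!is.null(boxes$neck)) fmt("neck", boxes$neck),
           fmt("top", boxes$top), fmt("low", boxes$low))
  writeLines(out, path)
  invisible(path)
}

#' Read normalized facial landmarks from JSON
#'
#' Expected shape: `{"image": str, "width": int, "height": int,
#' "points": [{"index": int, "x": float, "y": float}, ...]}` with `x`, `y`
#' normalized to `[0, 1]`.
#'
#' @param path JSON file path.
#' @return list with `image`, `width`, `height` and a data frame `points`.
#' @export
read_landmarks_json <- function(path) {
  tfm_abort_if(!file.exists(path), "parse_error",
    sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  tfm_abort_if(is.null(obj$points), "parse_error",
    sprintf("%s: no 'points' field", path))
  pts <- as.data.frame(obj$points)
  tfm_abort_if(!all(c("index", "x", "y") %in% names(pts)), "parse_error",
    sprintf("%s: points need index, x, y", path))
  list(image = obj$image, width = obj$width, height = obj$height,
       points = pts)
}

#' Save / load calibrated thresholds as JSON
#'
#' Numbers are serialized at full precision, so a load after save reproduces
#' the thresholds bit-exactly.
#'
#' @param thresholds an [nset_calibrate()] result.
#' @param path JSON file path.
#' @return `path` (write) or an `nset_thresholds` (read).
#' @export
write_thresholds_json <- function(thresholds, path) {
  m <- thresholds$metrics
  obj <- list(
    k = thresholds$k,
    cohort_n = thresholds$n,
    ddof = thresholds$ddof,
    metrics = stats::setNames(
      lapply(seq_len(nrow(m)), function(i)
        list(mu = m$mu[i], sigma = m$sigma[i], theta = m$theta[i])),
      m$metric)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  tfm_abort_if(!file.exists(path), "parse_error",
    sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  nm <- names(obj$metrics)
  structure(list(
    metrics = data.frame(
      metric = nm,
      mu = vapply(obj$metrics, function(x) x$mu, numeric(1)),
      sigma = vapply(obj$metrics, function(x) x$sigma, numeric(1)),
      theta = vapply(obj$metrics, function(x) x$theta, numeric(1)),
      row.names = NULL
    ),
    k = obj$k, n = obj$cohort_n, ddof = obj$ddof
  ), class = "nset_thresholds")
}

#' Run configuration
#'
#' Bundles every tunable constant of the three engines plus the seed; all
#' fields are validated by their module constructors at build time. The
#' configuration hash (MD5 of the canonical JSON serialization) changes
#' exactly when a field changes and is stamped into reports.
#'
#' @param eye an [eye_landmark_config()].
#' @param smue an [smue_config()].
#' @param nset an [nset_config()].
#' @param seed integer seed governing all randomness (phantoms, cohorts).
#' @return a list of class `run_config`.
#' @export
run_config <- function(eye = eye_landmark_config(), smue = smue_config(),
                       nset = nset_config(), seed = 1L) {
  structure(list(eye = eye, smue = smue, nset = nset,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Assemble a diagnostic report from eye and neck results
#'
#' Merges the quantitative outputs of the two pipelines into one
#' serializable record stamped with the tool version and configuration
#' hash; component values are passed through unaltered. No clinical label is
#' produced: classification from these measurements is left to downstream
#' users.
#'
#' @param sclera optional named list of [sclera_profile()]s (e.g. `left`,
#'   `right`).
#' @param comparison optional [profile_difference()] result.
#' @param neck optional `nset_result` or `nset_decision`.
#' @param config a [run_config()].
#' @param image_ids optional character vector of source image identifiers.
#' @return a list of class `diagnostic_report`.
#' @export
assemble_report <- function(sclera = NULL, comparison = NULL, neck = NULL,
                            config = run_config(), image_ids = character()) {
  tfm_abort_if(is.null(sclera) && is.null(neck), "empty_report",
    "report needs at least one of sclera profiles or a neck result")
  structure(list(
    image_ids = image_ids,
    sclera = sclera,
    comparison = comparison,
    neck = neck,
    version = as.character(utils::packageVersion("thyrofacemetrics")),
    config_hash = config_hash(config)
  ), class = "diagnostic_report")
}

#' Serialize a diagnostic report to JSON (and back)
#'
#' @param report a [assemble_report()] result.
#' @param path JSON file path.
#' @return `path` (write) or the parsed report list (read).
#' @export
write_report_json <- function(report, path) {
  enc <- list(
    image_ids = report$image_ids,
    sclera = if (!is.null(report$sclera)) lapply(report$sclera, function(p)
      list(side = attr(p, "side"), label = p$label, distance = p$distance,
           status = p$status)),
    comparison = if (!is.null(report$comparison)) {
      cmp <- report$comparison
      list(side = cmp$side, per_position_diff = as.list(cmp$per_position_diff),
           total_diff = cmp$total_diff, mean_diff = cmp$mean_diff,
           max_abs_position = cmp$max_abs_position, n_used = cmp$n_used)
    },
    neck = if (!is.null(report$neck)) {
      dec <- if (inherits(report$neck, "nset_result")) report$neck$decision
             else report$neck
      met <- if (inherits(report$neck, "nset_result")) report$neck$metrics
             else NULL
      list(metrics = if (!is.null(met)) unclass(met),
           votes = if (!is.null(dec)) as.list(dec$votes),
           score = if (!is.null(dec)) dec$score,
           result = if (!is.null(dec)) dec$result)
    },
    version = report$version,
    config_hash = report$config_hash
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  tfm_abort_if(!file.exists(path), "parse_error",
    sprintf("file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
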