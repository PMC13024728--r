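#' Scleral distance profile
#'
#' An ordered set of twelve eyelid-to-iris distances for one eye, measured in
#' unwrapped pixels at labeled reference positions (`L0`--`L11` or
#' `R0`--`R11`). This vector is the quantitative feature set a downstream
#' classifier can consume.
#'
#' @param side `"left"` or `"right"`.
#' @param labels character vector of position labels, in order.
#' @param distances numeric distances in unwrapped pixels (`NA` for missing).
#' @param status per-position status, `"ok"` or `"missing"`.
#' @param details optional data frame with per-position geometry.
#' @return a data frame of class `sclera_profile` with columns `label`,
#'   `distance`, `status` and attributes `side`, `details`.
#' @export
sclera_profile <- function(side, labels, distances,
                           status = rep("ok", length(distances)),
                           details = NULL) {
  side <- match.arg(side, c("left", "right"))
  tfm_abort_if(length(labels) != length(distances), "invalid_spec",
    "labels and distances must have equal length")
  tfm_abort_if(any(distances[status == "ok"] < 0, na.rm = TRUE), "invalid_spec",
    "distances must be >= 0")
  out <- data.frame(label = as.character(labels),
                    distance = as.numeric(distances),
                    status = as.character(status),
                    stringsAsFactors = FALSE)
  structure(out, side = side, details = details,
            class = c("sclera_profile", "data.frame"))
}

#' @export
print.sclera_profile <- function(x, ...) {
  cat(sprintf("<sclera_profile> side = %s, %d positions (%d missing)\n",
              attr(x, "side"), nrow(x), sum(x$status != "ok")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Compare two scleral profiles position by position
#'
#' Computes the signed per-position differences `a - b`, their total and
#' mean, and the label of the largest absolute difference (first on ties).
#' Positions missing in either profile are excluded from all sums; the count
#' of positions actually used is reported.
#'
#' @param a,b [sclera_profile()] objects with the same side and label order.
#' @return a list of class `profile_comparison`: `per_position_diff` (named),
#'   `total_diff`, `mean_diff`, `max_abs_position`, `max_abs_diff`, `n_used`,
#'   `side`.
#' @export
profile_difference <- function(a, b) {
  tfm_abort_if(!inherits(a, "sclera_profile") || !inherits(b, "sclera_profile"),
    "profile_mismatch", "both arguments must be sclera_profile objects")
  tfm_abort_if(!identical(attr(a, "side"), attr(b, "side")),
    "profile_mismatch", "profiles are for different sides")
  tfm_abort_if(!identical(a$label, b$label), "profile_mismatch",
    "profiles have different labels or label order")
  shared <- a$status == "ok" & b$status == "ok" &
    !is.na(a$distance) & !is.na(b$distance)
  tfm_abort_if(!any(shared), "profile_mismatch",
    "no shared non-missing positions to compare")
  diff <- a$distance[shared] - b$distance[shared]
  names(diff) <- a$label[shared]
  imax <- which.max(abs(diff))  # first index on ties
  structure(list(
    per_position_diff = diff,
    total_diff = sum(diff),
    mean_diff = sum(diff) / length(diff),
    max_abs_position = names(diff)[imax],
    max_abs_diff = diff[[imax]],
    n_used = length(diff),
    side = attr(a, "side")
  ), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> side = %s over %d positions\n",
              x$side, x$n_used))
  cat(sprintf("  total difference: %g px\n", x$total_diff))
  cat(sprintf("  mean difference:  %.2f px\n", x$mean_diff))
  cat(sprintf("  largest |difference| at %s: %g px\n",
              x$max_abs_position, x$max_abs_diff))
  invisible(x)
}

#' Published reference scleral profiles
#'
#' The worked patient-versus-normal example distances (in pixels) at the
#' twelve reference positions of each eye, shipped as plain CSV with the
#' package. Useful as a smoke test for [profile_difference()] and as a
#' reference profile for comparisons.
#'
#' @param group `"patient"` or `"normal"`.
#' @param side `"left"` or `"right"`.
#' @return a [sclera_profile()].
#' @export
sclera_reference_profile <- function(group = c("patient", "normal"),
                                     side = c("left", "right")) {
  group <- match.arg(group)
  side <- match.arg(side)
  path <- system.file("extdata", "reference_sclera_profiles.csv",
                      package = "thyrofacemetrics", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- tab[tab$group == group & tab$side == side, , drop = FALSE]
  rows <- rows[order(match(rows$label, paste0(toupper(substr(side, 1, 1)), 0:11))), ]
  sclera_profile(side = side, labels = rows$label, distances = rows$distance_px)
}

#' Write / read a scleral profile as CSV
#'
#' Columns `side`, `label`, `distance_px`, `status`; one row per reference
#' position. Floating point values survive the round trip bit-exactly.
#'
#' @param profile a [sclera_profile()].
#' @param path file path.
#' @return `path` (write) or a [sclera_profile()] (read).
#' @export
write_profile_csv <- function(profile, path) {
  out <- data.frame(side = attr(profile, "side"),
                    label = profile$label,
                    distance_px = format(profile$distance, digits = 17,
                                         scientific = FALSE, trim = TRUE),
                    status = profile$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tfm_abort_if(!file.exists(path), "parse_error", sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "label", "distance_px", "status")
  tfm_abort_if(!all(need %in% names(tab)), "parse_error",
    sprintf("profile CSV needs columns %s", paste(need, collapse = ", ")))
  sclera_profile(side = tab$side[1], labels = tab$label,
                 distances = as.numeric(tab$distance_px), status = tab$status)
}
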