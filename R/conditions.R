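# Classed error conditions. Every user-facing failure mode has a stable
# condition class ("tfm_<snake_case>") so callers and tests can catch it
# without matching message text.

tfm_error <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("tfm_", class), "tfm_error"),
    call = call
  ))
}

#' @keywords internal
tfm_abort_if <- function(cond, class, message) {
  if (isTRUE(cond)) tfm_error(class, message, call = sys.call(-1))
  invisible(NULL)
}
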