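# Classed conditions so callers can distinguish failure modes programmatically.
# Every error thrown by the package carries class c("kneemetry_<what>",
# "kneemetry_error", "error", "condition").

km_stop <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("kneemetry_", class), "kneemetry_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @noRd
km_assert <- function(ok, class, message) {
  if (!isTRUE(ok)) km_stop(class, message, call = sys.call(-2))
  invisible(TRUE)
}
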