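# Classed error conditions so callers can test failure modes precisely.
# Every error signalled by the package carries class c("sonotrack_<id>",
# "sonotrackError", "error", "condition").

st_stop <- function(id, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("sonotrack_", id), "sonotrackError")))
}

st_assert <- function(cond, id, msg, ...) {
  if (!isTRUE(cond)) st_stop(id, msg, ...)
  invisible(TRUE)
}
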