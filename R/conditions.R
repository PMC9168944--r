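# Classed conditions so callers (and the CLI) can distinguish bad input data
# from bad configuration and from programming errors.

rc_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "rc_error")))
}

rc_validation_error <- function(msg, ...) {
  rc_abort(msg, class = "rc_validation_error", ...)
}

rc_config_error <- function(msg, ...) {
  rc_abort(msg, class = "rc_config_error", ...)
}

rc_range_error <- function(msg, ...) {
  rc_abort(msg, class = c("rc_range_error", "rc_validation_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
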