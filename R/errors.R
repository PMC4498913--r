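# Structured conditions. Every error raised by the package carries the class
# "redese_error" plus a machine-readable code class such as "REJECT_SCHEMA",
# so callers can dispatch with tryCatch(..., REJECT_SCHEMA = ...).

redese_stop <- function(code, msg, ...) {
  stop(errorCondition(msg, ..., class = c(code, "redese_error", "error", "condition")))
}

redese_warn <- function(code, msg) {
  warning(warningCondition(msg, class = c(code, "redese_warning", "warning", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
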