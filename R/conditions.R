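# Classed error conditions so callers can distinguish failure modes
# programmatically (tryCatch(..., lq_invalid_geometry = ...)).

lq_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "lq_error")))
}

lq_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "lq_warning")))
}

stopifnot_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    lq_abort("lq_argument_error", sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
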