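# Classed error helpers so callers can distinguish failure modes.

gmphets_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "gmphets_error", "error", "condition")))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    gmphets_stop(sprintf("'%s' must be a finite numeric scalar", name), "parameter_error")
  invisible(x)
}
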