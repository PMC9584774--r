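# Classed conditions so callers (and the CLI) can map failures to exit codes.

grm_error <- function(class, msg) {
  stop(structure(
    class = c(class, "grm_error", "error", "condition"),
    list(message = msg, call = sys.call(-2))
  ))
}

abort_input    <- function(msg) grm_error("grm_input_error", msg)
abort_format   <- function(msg) grm_error("grm_format_error", msg)
abort_param    <- function(msg) grm_error("grm_parameter_error", msg)
abort_bounds   <- function(msg) grm_error("grm_bounds_error", msg)
abort_notfound <- function(msg) grm_error("grm_notfound_error", msg)
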