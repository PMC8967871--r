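# Structured conditions so callers (and tests) can discriminate failure
# modes without string matching.

stop_rpmc <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "rpmc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

stop_config <- function(field, message) {
  stop_rpmc("rpmc_config_error",
            sprintf("invalid configuration field '%s': %s", field, message),
            field = field)
}

stop_input <- function(message, ...) {
  stop_rpmc("rpmc_input_error", message, ...)
}
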