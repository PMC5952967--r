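# Typed condition helpers.  Every user-facing error in the package carries a
# class so callers (and the CLI) can map error kinds to exit codes.

stop_ncd <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ncd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_insufficient_data <- function(msg, ...) stop_ncd("ncd_insufficient_data", msg, ...)
stop_config            <- function(msg, ...) stop_ncd("ncd_config_error", msg, ...)
stop_parse             <- function(msg, ...) stop_ncd("ncd_parse_error", msg, ...)
stop_undefined_input   <- function(msg, ...) stop_ncd("ncd_undefined_input", msg, ...)
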