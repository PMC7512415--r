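# Typed error conditions so callers can distinguish degenerate inputs
# (constant series, no matches at tolerance r, too-short series) from
# programming errors. All inherit from "tempentropy_error".

stop_tempentropy <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tempentropy_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_short_series <- function(message) {
  stop_tempentropy(message, "tempentropy_short_series", call = sys.call(-1))
}

stop_degenerate <- function(message) {
  stop_tempentropy(message, "tempentropy_degenerate", call = sys.call(-1))
}

stop_undefined_entropy <- function(message) {
  stop_tempentropy(message, "tempentropy_undefined_entropy", call = sys.call(-1))
}

stop_parse <- function(message) {
  stop_tempentropy(message, "tempentropy_parse_error", call = sys.call(-1))
}
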