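# Classed conditions used throughout the package. Every error a pipeline
# stage can raise carries a class so callers (and measure_stoma) can react
# without string matching.

stop_stomapore <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message,
    class = c(paste0("stomapore_", class), "stomapore_error", "error", "condition"),
    call = call
  ))
}

stop_invalid <- function(message) stop_stomapore("invalid_argument", message, sys.call(-1))

is_stomapore_error <- function(e, class) {
  inherits(e, paste0("stomapore_", class))
}
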