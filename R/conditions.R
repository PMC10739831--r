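# Classed conditions so the CLI can map failures to exit codes:
# validation errors (bad arguments, unreadable config) -> exit 2,
# data errors (malformed/inconsistent input content)   -> exit 3.

psa_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "psa_error")))
}

validation_error <- function(msg) psa_stop(msg, "psa_validation_error")
data_error <- function(msg) psa_stop(msg, "psa_data_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
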