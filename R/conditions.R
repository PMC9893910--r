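#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish configuration
# problems (bad column maps, missing factors; exit code 2) from data
# validation / domain problems (negative loads, ETb < ETa; exit code 3).

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("basinfef_config_error", "basinfef_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("basinfef_validation_error", "basinfef_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("basinfef_domain_error", "basinfef_error")))
}

# scalar numeric check used by the arithmetic operations
check_num <- function(x, name) {
  if (!is.numeric(x) || anyNA(x))
    stop_domain("'%s' must be numeric and non-missing", name)
  invisible(x)
}
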