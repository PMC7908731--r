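#' @keywords internal
"_PACKAGE"

# Shared small helpers. Errors are classed so callers (and the CLI) can
# distinguish bad configuration from bad data.

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgdec_config_error", "error")))
}

abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgdec_data_error", "error")))
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# positive scalar check
check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_config(name, " must be a positive finite scalar")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
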