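#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the CLI) can distinguish bad inputs
# from I/O failures and from metrics that are undefined on the given data.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mcp_validation_error", "mcp_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mcp_io_error", "mcp_error")))
}

abort_undefined <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mcp_undefined_metric_error", "mcp_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Small stable fingerprint of an R object (polynomial hash over its
# deparsed form), used for the provenance block of CLI outputs.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    abort_validation("'%s' must be a single number in [0, 1], got %s",
                     name, paste(format(x), collapse = ", "))
  invisible(x)
}
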