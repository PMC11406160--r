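# Internal validation helpers shared across modules.

abort_domain <- function(msg) {
  rlang::abort(msg, class = "bitenet_domain_error")
}

abort_usage <- function(msg) {
  rlang::abort(msg, class = "bitenet_usage_error")
}

abort_schema <- function(msg) {
  rlang::abort(msg, class = "bitenet_schema_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "bitenet_validation_error")
}

# Require a strictly positive finite numeric vector; names the offending
# values in the error so bad rows are findable.
check_positive <- function(x, what) {
  if (!is.numeric(x)) {
    abort_domain(sprintf("%s must be numeric, got <%s>", what, class(x)[1]))
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    shown <- utils::head(bad, 5)
    abort_domain(sprintf(
      "%s must be positive and finite; offending value(s) %s at position(s) %s",
      what,
      paste(format(x[shown]), collapse = ", "),
      paste(shown, collapse = ", ")
    ))
  }
  invisible(x)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_domain(sprintf("%s must be finite numeric", what))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
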