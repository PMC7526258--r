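# internal helpers: classed conditions so callers can distinguish
# user-parameter errors from malformed input and degenerate data

abort_param <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "schictrans_parameter_error")
}

abort_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "schictrans_input_error")
}

abort_parse <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "schictrans_parse_error")
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "schictrans_degenerate_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scientific notation with 6 significant digits, stable across platforms
format_pval <- function(x) {
  sprintf("%.5e", x)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) && x >= min
}
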