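#' @keywords internal
"_PACKAGE"

## NULL-default helper, as in rlang but without the dependency
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ibosvm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ibosvm_error")))
}

#' Format a proportion as a percentage
#'
#' Converts a proportion in \[0, 1\] to a percentage rounded to a fixed number
#' of decimals, the scale used throughout the evaluation tables.
#'
#' @param x numeric vector of proportions.
#' @param digits decimal places to keep (default 2).
#' @return numeric vector of percentages.
#' @export
as_percent <- function(x, digits = 2) round(100 * x, digits)
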