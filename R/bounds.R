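#' Censored quantity bounds
#'
#' Permeabilities too fast to quantify are reported only as exceeding a
#' cutoff (e.g. "> 500e-6 cm/s"). Such values are carried through the
#' pipeline as typed bounds, never as plain numbers, so that downstream
#' arithmetic (efflux ratios, steady-state brain concentrations, uptake
#' half-lives) propagates the censoring direction instead of silently
#' degrading to a point value.
#'
#' A `bbb_bound` is a scalar with a `type`:
#' * `"point"` -- an ordinary measured value,
#' * `"lower"` -- the true value is known only to exceed `value` ("> v"),
#' * `"upper"` -- the true value is known only to be below `value` ("< v").
#'
#' @param value numeric scalar, the bound or point value.
#' @param type one of `"point"`, `"lower"`, `"upper"`.
#' @return An object of class `bbb_bound`.
#' @examples
#' b <- bound(500e-6, "lower")   # "> 500e-6"
#' bound_value(b)
#' bound_type(b)
#' format_bound(b)
#' @export
bound <- function(value, type = c("point", "lower", "upper")) {
  type <- match.arg(type)
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("bound value must be a single non-missing number", call. = FALSE)
  }
  structure(list(value = as.numeric(value), type = type), class = "bbb_bound")
}

#' @rdname bound
#' @param x object to test or query.
#' @export
is_bound <- function(x) inherits(x, "bbb_bound")

#' @rdname bound
#' @export
is_censored <- function(x) is_bound(x) && x$type != "point"

#' @rdname bound
#' @export
bound_value <- function(x) {
  if (is_bound(x)) x$value else as.numeric(x)
}

#' @rdname bound
#' @export
bound_type <- function(x) {
  if (is_bound(x)) x$type else "point"
}

#' Coerce a number or bound to a `bbb_bound`
#' @param x numeric scalar or `bbb_bound`.
#' @return A `bbb_bound`.
#' @export
as_bound <- function(x) {
  if (is_bound(x)) x else bound(x, "point")
}

#' Apply a strictly monotone transform to a bound
#'
#' The bound direction is preserved under increasing transforms and flipped
#' under decreasing ones (e.g. a reciprocal turns "> L" into "< 1/L").
#'
#' @param x a `bbb_bound` or numeric scalar.
#' @param f a strictly monotone function of one numeric argument.
#' @param decreasing logical; is `f` decreasing?
#' @return numeric when `x` is an uncensored point value, else `bbb_bound`.
#' @export
bound_transform <- function(x, f, decreasing = FALSE) {
  b <- as_bound(x)
  v <- f(b$value)
  if (b$type == "point") return(v)
  type <- if (!decreasing) b$type else c(lower = "upper", upper = "lower")[[b$type]]
  bound(v, type)
}

flip_type <- function(type) {
  switch(type, point = "point", lower = "upper", upper = "lower")
}

#' @rdname bound
#' @param digits significant digits for display.
#' @export
format_bound <- function(x, digits = 6) {
  b <- as_bound(x)
  prefix <- switch(b$type, point = "", lower = "> ", upper = "< ")
  paste0(prefix, format(signif(b$value, digits), scientific = FALSE,
                        trim = TRUE))
}

#' @export
format.bbb_bound <- function(x, ...) format_bound(x, ...)

#' @export
print.bbb_bound <- function(x, ...) {
  cat(format_bound(x), "\n")
  invisible(x)
}

# Encode a (possibly censored) scalar as a pair of CSV-safe columns.
bound_to_cols <- function(x) {
  b <- as_bound(x)
  list(value = b$value, bound_type = b$type)
}

cols_to_bound <- function(value, bound_type) {
  if (is.na(bound_type) || bound_type == "point") return(as.numeric(value))
  bound(value, bound_type)
}
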