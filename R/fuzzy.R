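#' Piecewise-linear fuzzy membership functions
#'
#' A fuzzy membership function maps a scalar feature value (in native feature
#' units, e.g. mm, mm^2, HU) to a confidence in `[0, 1]`. It is defined by an
#' ordered list of vertices `(value, confidence)`; evaluation interpolates
#' linearly between vertices and extrapolates flat beyond the first and last
#' vertex. These functions encode soft prior expectations for object features
#' in the knowledge base.
#'
#' @param values numeric vector of feature values, strictly increasing.
#' @param confidences numeric vector of confidences in `[0, 1]`, same length.
#' @return an object of class `fuzzy_function`.
#' @examples
#' f <- fuzzy_function(c(10000, 50000), c(0, 1))  # area in mm^2
#' eval_fuzzy(f, 30000)                           # 0.5
#' @export
fuzzy_function <- function(values, confidences) {
  values <- as.numeric(values)
  confidences <- as.numeric(confidences)
  if (length(values) < 1L || length(values) != length(confidences))
    stop("fuzzy_function needs >= 1 (value, confidence) vertex pair")
  if (any(diff(values) <= 0))
    stop("fuzzy vertex values must be strictly increasing")
  if (any(confidences < 0 | confidences > 1))
    stop("fuzzy confidences must lie in [0, 1]")
  structure(list(values = values, confidences = confidences),
            class = "fuzzy_function")
}

#' Evaluate a fuzzy membership function
#'
#' @param f a [fuzzy_function()].
#' @param x numeric vector of feature values.
#' @return confidences in `[0, 1]`, same length as `x`. Flat extrapolation
#'   outside the vertex range.
#' @export
eval_fuzzy <- function(f, x) {
  stopifnot(inherits(f, "fuzzy_function"))
  v <- f$values; c0 <- f$confidences
  if (length(v) == 1L) return(rep(c0, length(x)))
  out <- stats::approx(v, c0, xout = x, method = "linear",
                       yleft = c0[1L], yright = c0[length(c0)])$y
  out
}

#' Build a trapezoidal fuzzy function from a printed range
#'
#' Knowledge-base ranges such as "typically 50--100 mm" are turned into a
#' trapezoid with full confidence on `[a, b]` and linear shoulders of width
#' `shoulder * (b - a)` on each side (confidence 0 beyond the shoulders).
#'
#' @param a,b range endpoints (a < b), native units.
#' @param shoulder relative shoulder width, default 0.2.
#' @return a [fuzzy_function()].
#' @export
fuzzy_from_range <- function(a, b, shoulder = 0.2) {
  stopifnot(a < b, shoulder >= 0)
  s <- shoulder * (b - a)
  if (s == 0) {
    # crisp range: tiny epsilon shoulders keep vertices strictly increasing
    s <- .Machine$double.eps * max(1, abs(a), abs(b)) * 4
  }
  fuzzy_function(c(a - s, a, b, b + s), c(0, 1, 1, 0))
}

#' Fuzzy function for an absolute-tolerance expectation
#'
#' Full confidence for `|x| <= tol`, falling linearly to 0 at
#' `(1 + shoulder) * tol`. Used for "same level within d" expectations over an
#' absolute offset feature.
#'
#' @param tol tolerance (mm), > 0.
#' @param shoulder relative shoulder width, default 0.2.
#' @return a [fuzzy_function()].
#' @export
fuzzy_within <- function(tol, shoulder = 0.2) {
  stopifnot(tol > 0)
  s <- max(shoulder * tol, .Machine$double.eps * tol * 4)
  fuzzy_function(c(tol, tol + s), c(1, 0))
}

#' @export
print.fuzzy_function <- function(x, ...) {
  cat("fuzzy function,", length(x$values), "vertices:\n")
  cat(paste0("  (", format(x$values), ", ", format(x$confidences), ")"),
      sep = "\n")
  invisible(x)
}
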