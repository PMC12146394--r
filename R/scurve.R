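#' Decode a packed S-curve point code
#'
#' Crop parameter tables pack each point of a development S-curve into a
#' single decimal number: the digits before the decimal point give the
#' abscissa (percent of the growing season, or plants per square metre for
#' population curves) and the two digits after the decimal point give the
#' fraction of the maximum attained at that abscissa. For example the code
#' \code{10.19} on a leaf-area curve means "19\% of maximum leaf area at 10\%
#' of the season".
#'
#' @param code Packed decimal code, e.g. \code{10.19}. Must be positive with
#'   a non-zero fractional part.
#' @param x_scale Either \code{"percent"} (integer part is percent of season,
#'   returned divided by 100) or \code{"absolute"} (integer part returned
#'   as-is, e.g. plant density).
#' @return A named numeric vector \code{c(x = , y = )} with \code{y} in
#'   (0, 1).
#' @examples
#' decode_point_code(10.19, "percent")   # x = 0.10, y = 0.19
#' decode_point_code(4.99, "absolute")   # x = 4,    y = 0.99
#' @export
decode_point_code <- function(code, x_scale = c("percent", "absolute")) {
  x_scale <- match.arg(x_scale)
  stopifnot(is.numeric(code), length(code) == 1L, is.finite(code))
  if (code <= 0) stop("point code must be positive, got ", code)
  xi <- floor(code)
  y <- round((code - xi) * 100) / 100
  if (y <= 0 || y >= 1) {
    stop("fractional part of point code must encode a fraction in (0, 1), got ",
         format(code))
  }
  x <- if (x_scale == "percent") xi / 100 else xi
  if (x <= 0) stop("integer part of point code must be positive, got ", format(code))
  c(x = x, y = y)
}

#' Encode an S-curve point as a packed code
#'
#' Inverse of [decode_point_code()]: packs an (x, y) point back into the
#' single-number convention used in crop parameter tables.
#'
#' @param point Named numeric vector \code{c(x = , y = )}, \code{y} in (0, 1).
#' @param x_scale See [decode_point_code()].
#' @return The packed decimal code.
#' @export
encode_point_code <- function(point, x_scale = c("percent", "absolute")) {
  x_scale <- match.arg(x_scale)
  x <- point[["x"]]; y <- point[["y"]]
  if (y <= 0 || y >= 1) stop("y must be in (0, 1)")
  xi <- if (x_scale == "percent") round(x * 100) else round(x)
  if (xi <= 0) stop("x must round to a positive integer part")
  xi + round(y * 100) / 100
}

#' Fit the logistic S-curve through two points
#'
#' The development curves use the two-parameter form
#' \deqn{f(x) = \frac{x}{x + \exp(l_1 - l_2 x)}}
#' which rises from 0 at \eqn{x = 0} towards 1. Given two points with
#' \eqn{x_1 < x_2} and \eqn{y_1 < y_2} the coefficients follow from the exact
#' linearization \eqn{l_1 - l_2 x = \log(x (1 - y) / y)} as a 2-by-2 linear
#' solve.
#'
#' @param p1,p2 Points as returned by [decode_point_code()]; \code{p1} must
#'   precede \code{p2} in both coordinates.
#' @return An object of class \code{"scurve_coeffs"}: list with \code{l1},
#'   \code{l2}.
#' @examples
#' solve_scurve(c(x = 0.10, y = 0.19), c(x = 0.50, y = 0.95))
#' @export
solve_scurve <- function(p1, p2) {
  x <- c(p1[["x"]], p2[["x"]])
  y <- c(p1[["y"]], p2[["y"]])
  if (any(y <= 0 | y >= 1)) stop("point ordinates must be in (0, 1)")
  if (any(x <= 0)) stop("point abscissae must be positive")
  if (x[1] == x[2]) stop("points must have distinct abscissae")
  if (x[1] > x[2]) stop("p1 must precede p2 (x1 < x2)")
  if (y[1] >= y[2]) stop("curve must be increasing: need y1 < y2")
  rhs <- log(x * (1 - y) / y)
  A <- cbind(1, -x)
  sol <- solve(A, rhs)
  l1 <- sol[1]; l2 <- sol[2]
  if (l2 <= 0) stop("points imply a non-increasing curve (l2 <= 0)")
  structure(list(l1 = unname(l1), l2 = unname(l2)), class = "scurve_coeffs")
}

#' Evaluate the development S-curve
#'
#' @param x Abscissa value(s), \code{>= 0}.
#' @param coeffs An object from [solve_scurve()].
#' @return Fraction of maximum in \[0, 1); \code{f(0) = 0}, strictly
#'   increasing for \code{x > 0}.
#' @export
scurve_eval <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "scurve_coeffs"), all(x >= 0))
  denom <- x + exp(coeffs$l1 - coeffs$l2 * x)
  out <- ifelse(x == 0, 0, x / denom)
  pmin(pmax(out, 0), 1)
}

#' @export
print.scurve_coeffs <- function(x, ...) {
  cat(sprintf("S-curve f(x) = x / (x + exp(%.4f - %.4f x))\n", x$l1, x$l2))
  invisible(x)
}

#' Plant-population canopy factor
#'
#' Scales the maximum attainable leaf area index by plant density, using an
#' S-curve through the two decoded population points (absolute x scale,
#' plants per square metre).
#'
#' @param density Plants per square metre, \code{>= 0}.
#' @param ppl1,ppl2 Decoded population points (see [decode_point_code()] with
#'   \code{x_scale = "absolute"}).
#' @return Fraction of maximum LAI in \[0, 1\]; 0 at zero density,
#'   nondecreasing in density.
#' @export
population_factor <- function(density, ppl1, ppl2) {
  stopifnot(all(density >= 0))
  scurve_eval(density, solve_scurve(ppl1, ppl2))
}
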