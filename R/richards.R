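#' The four-parameter Richards growth function
#'
#' Evaluates the generalized-logistic (Richards) sigmoid
#' \deqn{y(x) = a \left(1 + b e^{-cx}\right)^{-1/d}}
#' which rises monotonically from 0 towards the asymptote `a`. With shape
#' `d = 1` it reduces to the ordinary logistic. `x` is the explanatory
#' variable of the growth series: day of year, or accumulated degree days
#' when the series has been re-expressed on a thermal-time axis.
#'
#' @param x Numeric vector of x-values (day of year or degree days).
#' @param a Asymptotic stem length (cm); must be > 0.
#' @param b Scale/offset parameter (dimensionless); must be > 0.
#' @param c Rate parameter (per x-unit); must be > 0.
#' @param d Shape parameter (dimensionless); must be > 0.
#'
#' @return Numeric vector of stem lengths (cm), strictly between 0 and `a`.
#' @examples
#' richards_value(0, a = 300, b = 100, c = 0.08, d = 1)    # a / (1 + b)
#' richards_value(c(50, 100, 200), 300, 100, 0.08, 1)
#' @export
richards_value <- function(x, a, b, c, d) {
  check_richards_params(a, b, c, d)
  # evaluate on the log scale: b * exp(-c x) overflows for early x when b is
  # large, but log1p(exp(.)) is stable throughout
  a * exp(-log1p(exp(log(b) - c * x)) / d)
}

#' First derivative (growth rate) of the Richards function
#'
#' @inheritParams richards_value
#' @return Growth rate in cm per x-unit, positive everywhere.
#' @examples
#' richards_deriv(57.56, 300, 100, 0.08, 1) # close to the maximum rate
#' @export
richards_deriv <- function(x, a, b, c, d) {
  check_richards_params(a, b, c, d)
  # y' = (a c / d) u (1 + u)^(-1/d - 1),  u = b exp(-c x)
  lu <- log(b) - c * x
  l1u <- log1p(exp(lu))
  (a * c / d) * exp(lu - (1 / d + 1) * l1u)
}

#' Second derivative (curvature) of the Richards function
#'
#' The logarithmic growth phase is delimited by the two curvature extrema:
#' the maximum of the second derivative marks its start, the minimum its
#' end.
#'
#' @inheritParams richards_value
#' @return Second derivative in cm per x-unit squared.
#' @export
richards_deriv2 <- function(x, a, b, c, d) {
  check_richards_params(a, b, c, d)
  # y'' = -(a c^2 / d) u (1 - u/d) (1 + u)^(-1/d - 2)
  lu <- log(b) - c * x
  u <- exp(lu)
  l1u <- log1p(u)
  -(a * c^2 / d) * (1 - u / d) * exp(lu - (1 / d + 2) * l1u)
}

#' Definite integral of the Richards function
#'
#' Area under the fitted growth curve (AUC) over a window, by adaptive
#' quadrature. Units are cm times x-units (cm-days on the day-of-year
#' axis).
#'
#' @inheritParams richards_value
#' @param lower,upper Integration window; `lower < upper`.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return Scalar integral value.
#' @examples
#' richards_auc(300, 100, 0.08, 1, lower = 0, upper = 365)
#' @export
richards_auc <- function(a, b, c, d, lower = 0, upper = 365,
                         rel_tol = 1e-10) {
  check_richards_params(a, b, c, d)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    abort("`lower` must be strictly less than `upper`.",
          class = "stemseason_domain_error")
  }
  stats::integrate(richards_value, lower, upper, a = a, b = b, c = c, d = d,
                   rel.tol = rel_tol, subdivisions = 500L)$value
}

#' Invert the Richards function: x at a given stem height
#'
#' Solves \eqn{y(x) = h} in closed form,
#' \deqn{x = -\frac{1}{c}\,\ln\!\frac{(a/h)^d - 1}{b},}
#' used to compute the day of year (or accumulated degree days) at which a
#' plant reaches a reference height such as 15 cm.
#'
#' @inheritParams richards_value
#' @param h Target stem length (cm); must satisfy `0 < h < a`.
#' @return The x-value at which the curve attains `h`.
#' @examples
#' day_at_height(15, 300, 100, 0.08, 1)
#' @export
day_at_height <- function(h, a, b, c, d) {
  check_richards_params(a, b, c, d)
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`h` must be positive and finite.",
          class = "stemseason_domain_error")
  }
  if (any(h >= a)) {
    abort(
      "`h` is at or above the asymptote `a`; the curve never reaches it.",
      class = "stemseason_unreachable_height_error"
    )
  }
  -(1 / c) * log(expm1(d * (log(a) - log(h))) / b)
}

#' Closed-form growth characteristics of a Richards curve
#'
#' Computes, analytically, the x at maximum growth rate
#' \eqn{x^\ast = \ln(b/d)/c}, the maximum rate itself
#' \eqn{\mathrm{MaxGR} = a c (1+d)^{-(d+1)/d}}, and the curvature extrema
#' delimiting the logarithmic growth phase. Writing \eqn{u = b e^{-cx}},
#' the third derivative vanishes at the roots of
#' \eqn{u^2 - d(d+3)u + d^2 = 0}; the larger root gives the start and the
#' smaller the end of the phase. Because the root product is \eqn{d^2},
#' the two extrema are symmetric about \eqn{x^\ast} on the x-axis.
#'
#' @inheritParams richards_value
#' @return A list with `day_max_gr`, `max_gr`, `start_logg`, `end_logg`,
#'   `duration`.
#' @examples
#' richards_characteristics(300, 100, 0.08, 1)
#' @export
richards_characteristics <- function(a, b, c, d) {
  check_richards_params(a, b, c, d)
  x_star <- log(b / d) / c
  max_gr <- a * c * (1 + d)^(-(d + 1) / d)
  disc <- sqrt((d + 3)^2 - 4)
  u_hi <- d / 2 * ((d + 3) + disc)
  u_lo <- d / 2 * ((d + 3) - disc)
  start_logg <- log(b / u_hi) / c
  end_logg <- log(b / u_lo) / c
  list(
    day_max_gr = x_star,
    max_gr = max_gr,
    start_logg = start_logg,
    end_logg = end_logg,
    duration = end_logg - start_logg
  )
}

check_richards_params <- function(a, b, c, d, call = rlang::caller_env()) {
  bad <- !is.finite(c(a, b, c, d)) | c(a, b, c, d) <= 0
  if (any(bad)) {
    abort(
      paste0(
        "Richards parameters must all be positive and finite; got a = ", a,
        ", b = ", b, ", c = ", c, ", d = ", d, "."
      ),
      class = "stemseason_parameter_error", call = call
    )
  }
  invisible(TRUE)
}
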