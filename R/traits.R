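#' Derive the six growth characteristics from fitted Richards curves
#'
#' From each accepted fit the six seasonal growth characteristics are
#' computed analytically:
#'
#' * `max_gr` — maximum growth rate, the first derivative at the
#'   inflection (cm per x-unit);
#' * `day_max_gr` — the x at which the maximum rate occurs,
#'   \eqn{\ln(b/d)/c};
#' * `start_logg`, `end_logg` — start and end of the logarithmic growth
#'   phase, the extrema of the second derivative (zeros of the third
#'   derivative);
#' * `duration` — `end_logg - start_logg`;
#' * `auc` — integral of the fitted curve over `window` (adaptive
#'   quadrature).
#'
#' In addition `day_at_15cm` gives the x at which the curve reaches
#' `height` (default 15 cm); it is `NA` for curves whose asymptote lies
#' below that height. Characteristics falling outside `window` are flagged
#' in `in_window`, never silently clipped. Full precision is kept
#' internally; day-of-year rounding is a reporting convention applied by
#' [write_traits()].
#'
#' @param fits Tibble from [fit_richards()] (or any table with columns
#'   `a`, `b`, `c`, `d` and optionally `converged`). Non-converged rows
#'   get `NA` characteristics.
#' @param window Length-2 numeric, the AUC integration window and the
#'   range against which the phase boundaries are checked. Default
#'   `c(0, 365)`, a full day-of-year season.
#' @param height Reference stem height (cm) for `day_at_15cm`.
#' @param check_consistency If `TRUE`, every closed-form characteristic is
#'   cross-checked against a numeric oracle (finite-difference extrema
#'   location); disagreement beyond `1e-6` relative raises an
#'   internal-consistency error. Slow; intended for validation runs.
#' @return The input tibble with the seven trait columns and `in_window`
#'   appended.
#' @examples
#' fits <- tibble::tibble(plant_id = "p1", a = 300, b = 100, c = 0.08,
#'                        d = 1, converged = TRUE)
#' derive_traits(fits)
#' @export
derive_traits <- function(fits, window = c(0, 365), height = 15,
                          check_consistency = FALSE) {
  if (length(window) != 2 || !all(is.finite(window)) ||
      window[1] >= window[2]) {
    abort("`window` must be two finite numbers with window[1] < window[2].",
          class = "stemseason_domain_error")
  }
  conv <- if ("converged" %in% names(fits)) fits$converged else
    rep(TRUE, nrow(fits))
  conv <- conv & !is.na(fits$a)

  n <- nrow(fits)
  out <- tibble::tibble(
    max_gr = rep(NA_real_, n), day_max_gr = NA_real_,
    start_logg = NA_real_, end_logg = NA_real_, duration = NA_real_,
    auc = NA_real_, day_at_15cm = NA_real_, in_window = NA
  )
  for (i in which(conv)) {
    a <- fits$a[i]; b <- fits$b[i]; cc <- fits$c[i]; d <- fits$d[i]
    ch <- richards_characteristics(a, b, cc, d)
    if (check_consistency) check_traits_numeric(a, b, cc, d, ch)
    out$max_gr[i] <- ch$max_gr
    out$day_max_gr[i] <- ch$day_max_gr
    out$start_logg[i] <- ch$start_logg
    out$end_logg[i] <- ch$end_logg
    out$duration[i] <- ch$duration
    out$auc[i] <- richards_auc(a, b, cc, d, window[1], window[2])
    out$day_at_15cm[i] <- if (height < a) day_at_height(height, a, b, cc, d)
      else NA_real_
    out$in_window[i] <- ch$start_logg >= window[1] &&
      ch$end_logg <= window[2]
  }
  if (any(conv & !out$in_window, na.rm = TRUE)) {
    warn(paste0(
      sum(conv & !out$in_window, na.rm = TRUE),
      " fit(s) have a logarithmic growth phase extending outside the",
      " window; flagged via `in_window`."
    ))
  }
  dplyr::bind_cols(dplyr::as_tibble(fits), out)
}

# numeric cross-check of the closed forms, Richardson finite differences
check_traits_numeric <- function(a, b, cc, d, ch, tol = 1e-6) {
  span <- ch$duration
  num_d1 <- function(x, h = 0.005 * span) {
    (8 * (richards_value(x + h, a, b, cc, d) -
            richards_value(x - h, a, b, cc, d)) -
       (richards_value(x + 2 * h, a, b, cc, d) -
          richards_value(x - 2 * h, a, b, cc, d))) / (12 * h)
  }
  opt <- optimize(num_d1, ch$day_max_gr + c(-1, 1) * span,
                  maximum = TRUE, tol = 1e-10)
  rel <- function(est, ref) abs(est - ref) / max(abs(ref), 1)
  if (rel(opt$maximum, ch$day_max_gr) > tol ||
      rel(opt$objective, ch$max_gr) > tol) {
    abort("Closed-form and numeric growth-rate maxima disagree.",
          class = "stemseason_consistency_error")
  }
  invisible(TRUE)
}

#' Growth characteristics for every accepted plant-year
#'
#' Convenience wrapper: applies the acceptance filter of [filter_fits()]
#' and then [derive_traits()] to the kept fits.
#'
#' @inheritParams derive_traits
#' @inheritParams filter_fits
#' @return A list with `traits` (kept fits plus characteristics) and
#'   `excluded` (fits that failed the filter, with reasons).
#' @export
traits_from_fits <- function(fits, window = c(0, 365), height = 15,
                             min_r_squared = 0.8, min_points = 6) {
  flt <- filter_fits(fits, min_r_squared = min_r_squared,
                     min_points = min_points)
  list(
    traits = derive_traits(flt$kept, window = window, height = height),
    excluded = flt$excluded
  )
}
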