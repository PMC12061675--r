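#' Daily degree days above a base temperature
#'
#' Heat accumulation for one day from the daily maximum and minimum air
#' temperatures, above a lower threshold (10 degrees C by default, the
#' conventional base for warm-season grasses).
#'
#' Two standard methods are provided:
#' * `"average"` — `max(0, (tmax + tmin)/2 - t_base)`;
#' * `"single_sine"` — the day's temperature course is modelled as one
#'   sine cycle between `tmin` and `tmax` and the area above `t_base` is
#'   taken analytically (Baskerville-Emin): with amplitude
#'   `A = (tmax - tmin)/2`, mean `m`, and `theta = asin((t_base - m)/A)`,
#'   the degree days are `((m - t_base) * (pi/2 - theta) + A*cos(theta))/pi`
#'   when the threshold cuts the cycle.
#'
#' The sine method credits above-threshold hours on days whose mean is
#' below base, so it is never smaller than the average method when
#' `tmin < t_base < tmax`. No upper threshold is applied.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature (degrees C);
#'   vectors are recycled to common length. `tmax >= tmin` is required.
#' @param t_base Base temperature (degrees C), default 10.
#' @param method `"average"` (default) or `"single_sine"`.
#' @return Degree days (degrees C times days), non-negative.
#' @examples
#' daily_degree_days(20, 10)                       # 5
#' daily_degree_days(14, 2, method = "single_sine")
#' @export
daily_degree_days <- function(tmax, tmin, t_base = 10,
                              method = c("average", "single_sine")) {
  method <- match.arg(method)
  if (any(tmax < tmin)) {
    abort("`tmax` must be >= `tmin`.", class = "stemseason_domain_error")
  }
  m <- (tmax + tmin) / 2
  if (method == "average") {
    return(pmax(0, m - t_base))
  }
  amp <- (tmax - tmin) / 2
  dd <- numeric(length(m))
  above <- tmin >= t_base
  below <- tmax <= t_base
  cut <- !above & !below
  dd[above] <- m[above] - t_base
  theta <- asin(pmin(pmax((t_base - m[cut]) / amp[cut], -1), 1))
  dd[cut] <- ((m[cut] - t_base) * (pi / 2 - theta) +
                amp[cut] * cos(theta)) / pi
  dd
}

#' Accumulate thermal time over a season
#'
#' Converts a daily weather table to daily and cumulative degree days.
#' Days must be consecutive: missing weather days are a hard error, never
#' silently interpolated — supply a gap-filled series explicitly.
#'
#' @param weather Data frame with columns `day` (day of year, 1-based
#'   integer), `tmax_c`, `tmin_c`.
#' @inheritParams daily_degree_days
#' @return A tibble with `day`, `daily_dd`, `cumulative_dd`; the method
#'   and base temperature are recorded as attributes `dd_method` and
#'   `t_base`.
#' @examples
#' w <- tibble::tibble(day = 1:10, tmax_c = 20, tmin_c = 10)
#' accumulate_thermal_time(w)
#' @export
accumulate_thermal_time <- function(weather, t_base = 10,
                                    method = c("average", "single_sine")) {
  method <- match.arg(method)
  require_columns(weather, c("day", "tmax_c", "tmin_c"), "weather")
  weather <- dplyr::arrange(weather, .data$day)
  if (nrow(weather) > 1 && any(diff(weather$day) != 1)) {
    gaps <- weather$day[which(diff(weather$day) != 1)]
    abort(
      paste0("Weather days are not consecutive (gap after day ",
             paste(head(gaps, 3), collapse = ", "), ")."),
      class = "stemseason_gap_error"
    )
  }
  daily <- daily_degree_days(weather$tmax_c, weather$tmin_c,
                             t_base = t_base, method = method)
  out <- tibble::tibble(
    day = weather$day,
    daily_dd = daily,
    cumulative_dd = cumsum(daily)
  )
  attr(out, "dd_method") <- method
  attr(out, "t_base") <- t_base
  out
}

#' Re-express a stem series on the thermal-time axis
#'
#' Replaces each measurement's day of year with the accumulated degree
#' days at that day. Ordering is preserved because cumulative degree days
#' are non-decreasing in the day. Measurement days not covered by the
#' thermal series are an error.
#'
#' @param series Data frame of measurements with a `day` column (plus any
#'   identifier columns, which are preserved).
#' @param thermal Tibble from [accumulate_thermal_time()].
#' @return `series` with a `thermal_cd` column appended.
#' @export
reexpress_series <- function(series, thermal) {
  require_columns(series, "day", "series")
  require_columns(thermal, c("day", "cumulative_dd"), "thermal")
  idx <- match(series$day, thermal$day)
  if (anyNA(idx)) {
    missing_days <- sort(unique(series$day[is.na(idx)]))
    abort(
      paste0("Measurement day(s) not covered by the weather series: ",
             paste(head(missing_days, 5), collapse = ", "), "."),
      class = "stemseason_coverage_error"
    )
  }
  dplyr::mutate(dplyr::as_tibble(series),
                thermal_cd = thermal$cumulative_dd[idx])
}
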