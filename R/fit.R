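#' Fit a Richards curve to one stem-elongation series
#'
#' Bounded nonlinear least squares via [minpack.lm::nlsLM()]
#' (Levenberg-Marquardt), with data-driven starting values and multi-start
#' restarts. Richards fits are initialization-sensitive, so the starting
#' point is built from the data: `a0 = 1.05 * max(y)`, `d0 = 1`, `c0` from
#' the slope of a log-linearized logistic on the interior points, and `b0`
#' solved from the first observation. If the first attempt fails to
#' converge (or leaves residual variance unexplained), up to `n_restarts`
#' further attempts jitter `(b, c, d)` log-uniformly around the start.
#'
#' @param x Numeric vector of x-values (strictly increasing).
#' @param y Numeric vector of stem lengths (cm, non-negative), same length
#'   as `x`.
#' @param min_points Minimum number of observations required (default 6).
#' @param n_restarts Maximum number of jittered restarts (default 20).
#' @param lower,upper Parameter bounds, in the order `(a, b, c, d)`, as
#'   multipliers/values documented in the defaults. `a` is bounded in
#'   `(0.5 * max(y), 10 * max(y)]` (the asymptote may lie below the
#'   noisiest plateau observation), `b` in `(1e-6, 1e8]`, `c` in `(1e-4, 1]`,
#'   `d` in `(0.05, 20]`. The wide `b` range matters: a plant whose
#'   inflection falls late in the season at a brisk rate has
#'   `b = d * exp(c * DayMaxGR)` in the millions.
#'
#' @return An object of class `richards_fit`: a list with elements
#'   `params` (named vector a, b, c, d), `rss`, `r_squared`, `n_points`,
#'   `converged`, `n_restarts_used`, and the fitting `data`.
#'   Non-convergent fits are returned with `converged = FALSE`, never
#'   silently as trait inputs.
#' @seealso [fit_richards()] for the data-frame interface,
#'   [derive_traits()] for the growth characteristics.
#' @examples
#' x <- seq(20, 200, by = 14)
#' y <- richards_value(x, 300, 100, 0.08, 1)
#' fit <- fit_richards_one(x, y)
#' coef(fit)
#' @export
fit_richards_one <- function(x, y, min_points = 6, n_restarts = 20,
                             lower = NULL, upper = NULL) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "stemseason_domain_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (is.unsorted(x, strictly = TRUE)) {
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
    if (anyDuplicated(x)) {
      abort("`x` values must be distinct.", class = "stemseason_domain_error")
    }
  }
  if (length(x) < min_points || sum(y > 0) < 2) {
    abort(
      paste0("Need at least ", min_points,
             " points (and two positive lengths) to fit; got ",
             length(x), "."),
      class = "stemseason_insufficient_data_error"
    )
  }
  y_max <- max(y)
  # the asymptote may sit below the largest observation when plateau
  # measurements overshoot, so its lower bound must leave room under
  # max(y)
  lower <- lower %||% c(a = 0.5 * y_max, b = 1e-6, c = 1e-4, d = 0.05)
  upper <- upper %||% c(a = 10 * y_max, b = 1e8, c = 1, d = 20)

  start <- richards_start(x, y, lower, upper)
  tss <- sum((y - mean(y))^2)
  dat <- data.frame(x = x, y = y)

  best <- NULL
  n_used <- 0L
  for (i in seq_len(n_restarts + 1L)) {
    st <- if (i == 1L) start else jitter_start(start, lower, upper)
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ a * (1 + b * exp(-c * x))^(-1 / d),
      data = dat, start = as.list(st),
      lower = unname(lower), upper = unname(upper),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), silent = TRUE)
    n_used <- i
    if (!inherits(fit, "try-error")) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(fit = fit, rss = rss)
      }
      # accept once the fit explains the series well; otherwise allow a
      # handful of restarts to escape a possible local optimum
      if (tss == 0 || best$rss <= 0.05 * tss) break
      if (i >= 6L) break
    }
  }

  if (is.null(best)) {
    out <- list(
      params = c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_),
      rss = NA_real_, r_squared = NA_real_, n_points = length(x),
      converged = FALSE, n_restarts_used = n_used, data = dat
    )
    class(out) <- "richards_fit"
    return(out)
  }

  pars <- coef(best$fit)[c("a", "b", "c", "d")]
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  out <- list(
    params = pars,
    rss = best$rss,
    r_squared = max(0, min(1, r2)),
    n_points = length(x),
    converged = TRUE,
    n_restarts_used = n_used,
    data = dat
  )
  class(out) <- "richards_fit"
  out
}

richards_start <- function(x, y, lower, upper) {
  a0 <- 1.05 * max(y)
  # log-linearize a logistic on interior points: log(a0/y - 1) ~ log b - c x
  interior <- y > 0.05 * a0 & y < 0.95 * a0
  if (sum(interior) >= 2) {
    z <- log(pmax(a0 / y[interior] - 1, 1e-8))
    sl <- coef(lm(z ~ x[interior]))
    c0 <- max(-unname(sl[2]), 1e-3)
    b0 <- exp(unname(sl[1]))
  } else {
    c0 <- 0.05
    y1 <- max(min(y[y > 0]), 1e-3)
    b0 <- (a0 / y1 - 1) * exp(c0 * x[which(y > 0)[1]])
  }
  st <- c(a = a0, b = b0, c = c0, d = 1)
  pmin(pmax(st, lower * 1.0000001), upper)
}

jitter_start <- function(start, lower, upper) {
  st <- start
  st[c("b", "c", "d")] <- st[c("b", "c", "d")] *
    exp(runif(3, -log(4), log(4)))
  pmin(pmax(st, lower * 1.0000001), upper)
}

#' Fit Richards curves to every plant-year in a long table
#'
#' Maps [fit_richards_one()] over the groups defined by `id_cols` and
#' returns one row per plant-year with the fitted parameters and fit
#' diagnostics. Groups with fewer than `min_points` observations (or
#' without two positive lengths) are returned with `converged = FALSE` and
#' an `exclusion_reason` rather than dropped, so that every series is
#' accounted for downstream.
#'
#' @param data Long-format data frame with one row per measurement.
#' @param x,y Names (strings) of the x and length columns; defaults `"day"`
#'   and `"length_cm"`.
#' @param id_cols Character vector of grouping columns identifying one
#'   series (default `c("plant_id", "year")`; missing ones are ignored).
#' @inheritParams fit_richards_one
#' @return A tibble with `id_cols`, `a`, `b`, `c`, `d`, `rss`,
#'   `r_squared`, `n_points`, `converged`, `n_restarts_used`,
#'   `exclusion_reason` (NA for fitted series).
#' @examples
#' sim <- simulate_trial(sim_config(n_genotypes = 4, seed = 1))
#' fits <- fit_richards(sim$measurements)
#' fits
#' @export
fit_richards <- function(data, x = "day", y = "length_cm",
                         id_cols = c("plant_id", "year"),
                         min_points = 6, n_restarts = 20) {
  id_cols <- intersect(id_cols, names(data))
  if (length(id_cols) == 0) {
    abort("None of `id_cols` are present in `data`.",
          class = "stemseason_schema_error")
  }
  for (col in c(x, y)) {
    if (!col %in% names(data)) {
      abort(paste0("Column `", col, "` not found in `data`."),
            class = "stemseason_schema_error")
    }
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::group_modify(function(df, key) {
      fit <- tryCatch(
        fit_richards_one(df[[x]], df[[y]], min_points = min_points,
                         n_restarts = n_restarts),
        stemseason_insufficient_data_error = function(e) e
      )
      if (inherits(fit, "error")) {
        return(tibble::tibble(
          a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
          rss = NA_real_, r_squared = NA_real_, n_points = nrow(df),
          converged = FALSE, n_restarts_used = 0L,
          exclusion_reason = "insufficient_data"
        ))
      }
      tibble::tibble(
        a = fit$params[["a"]], b = fit$params[["b"]],
        c = fit$params[["c"]], d = fit$params[["d"]],
        rss = fit$rss, r_squared = fit$r_squared,
        n_points = fit$n_points, converged = fit$converged,
        n_restarts_used = fit$n_restarts_used,
        exclusion_reason = if (fit$converged) NA_character_ else
          "non_convergence"
      )
    }) |>
    dplyr::ungroup()
}

#' Apply the fit-acceptance filter
#'
#' A plant-year enters the downstream analyses only if its fit converged,
#' used at least `min_points` observations, and explains the series with
#' `r_squared >= min_r_squared` (default 0.8). Excluded fits are returned
#' alongside, each with a machine-readable reason.
#'
#' @param fits Tibble from [fit_richards()].
#' @param min_r_squared Minimum goodness of fit (default 0.8).
#' @param min_points Minimum observation count (default 6).
#' @return A list with `kept` and `excluded` tibbles; `excluded` carries an
#'   `exclusion_reason` column.
#' @export
filter_fits <- function(fits, min_r_squared = 0.8, min_points = 6) {
  reason <- dplyr::case_when(
    !fits$converged ~ dplyr::coalesce(fits$exclusion_reason,
                                      "non_convergence"),
    fits$n_points < min_points ~ "too_few_points",
    is.na(fits$r_squared) | fits$r_squared < min_r_squared ~ "low_r_squared",
    .default = NA_character_
  )
  keep <- is.na(reason)
  list(
    kept = dplyr::as_tibble(fits[keep, , drop = FALSE]),
    excluded = dplyr::mutate(
      dplyr::as_tibble(fits[!keep, , drop = FALSE]),
      exclusion_reason = reason[!keep]
    )
  )
}

#' @export
print.richards_fit <- function(x, ...) {
  cat("Richards growth fit (", x$n_points, " points)\n", sep = "")
  if (x$converged) {
    cat(sprintf("  a = %.3f, b = %.4g, c = %.5f, d = %.4f\n",
                x$params[["a"]], x$params[["b"]], x$params[["c"]],
                x$params[["d"]]))
    cat(sprintf("  rss = %.4g, R-squared = %.4f (restarts used: %d)\n",
                x$rss, x$r_squared, x$n_restarts_used))
  } else {
    cat("  did not converge after", x$n_restarts_used, "attempts\n")
  }
  invisible(x)
}

#' @export
coef.richards_fit <- function(object, ...) object$params

#' @rdname fit_richards_one
#' @param object,x A `richards_fit` object.
#' @param ... Unused.
#' @method tidy richards_fit
#' @export
tidy.richards_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "d"),
    estimate = unname(x$params)
  )
}

#' @rdname fit_richards_one
#' @method glance richards_fit
#' @export
glance.richards_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, r_squared = x$r_squared, n_points = x$n_points,
    converged = x$converged, n_restarts_used = x$n_restarts_used
  )
}

#' @rdname fit_richards_one
#' @method augment richards_fit
#' @export
augment.richards_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$data)
  if (x$converged) {
    p <- x$params
    out$.fitted <- richards_value(out$x, p[["a"]], p[["b"]], p[["c"]],
                                  p[["d"]])
    out$.resid <- out$y - out$.fitted
  }
  out
}
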