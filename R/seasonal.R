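#' Bin plants by duration of the logarithmic growth phase
#'
#' Plants with a similar duration are grouped so that the seasonal timing
#' of growth can be related to yield without the confounding rate-duration
#' tradeoff. Bins are aligned to multiples of `bin_width` starting at 0
#' (10-day bins are `[40, 50)`, `[50, 60)`, ...); bins holding fewer than
#' `min_count` plants are discarded. Every retained plant falls in exactly
#' one bin.
#'
#' @param data Trait table with a `duration` column (days).
#' @param bin_width Bin width in days; the analysis is typically run at
#'   widths between 3 and 10 days (default 10).
#' @param min_count Minimum plants per retained bin (default 10).
#' @param duration Name of the duration column.
#' @return The input rows of retained bins, with `bin_lo` and `bin_hi`
#'   columns appended; the full bin census (including discarded bins) is
#'   attached as attribute `"bins"`, a tibble of `bin_lo`, `bin_hi`, `n`,
#'   `retained`.
#' @examples
#' d <- tibble::tibble(duration = runif(100, 40, 120), dw = rnorm(100))
#' binned <- bin_by_duration(d)
#' attr(binned, "bins")
#' @export
bin_by_duration <- function(data, bin_width = 10, min_count = 10,
                            duration = "duration") {
  if (bin_width <= 0) {
    abort("`bin_width` must be positive.",
          class = "stemseason_domain_error")
  }
  require_columns(data, duration, "data")
  data <- dplyr::as_tibble(data)
  if (nrow(data) == 0) {
    out <- dplyr::mutate(data, bin_lo = numeric(0), bin_hi = numeric(0))
    attr(out, "bins") <- tibble::tibble(bin_lo = numeric(0),
                                        bin_hi = numeric(0),
                                        n = integer(0),
                                        retained = logical(0))
    return(out)
  }
  lo <- floor(data[[duration]] / bin_width) * bin_width
  data$bin_lo <- lo
  data$bin_hi <- lo + bin_width
  census <- data |>
    dplyr::count(.data$bin_lo, .data$bin_hi, name = "n") |>
    dplyr::arrange(.data$bin_lo) |>
    dplyr::mutate(retained = .data$n >= min_count)
  out <- dplyr::semi_join(
    data, dplyr::filter(census, .data$retained),
    by = c("bin_lo", "bin_hi")
  )
  attr(out, "bins") <- census
  out
}

#' Within-bin Pearson correlations
#'
#' Correlates two traits within each retained duration bin, flagging
#' significance at `alpha`. This is the step that asks whether, among
#' plants whose logarithmic phase lasted equally long, an earlier start of
#' growth is associated with higher yield or faster growth.
#'
#' @param binned Output of [bin_by_duration()].
#' @param x_trait,y_trait Names of the trait columns to correlate
#'   (defaults `"start_logg"` and `"dw"`).
#' @param alpha Significance level (default 0.05, no multiplicity
#'   correction).
#' @return A tibble with one row per bin: `bin_lo`, `bin_hi`, `n`,
#'   `x_trait`, `y_trait`, `r`, `p`, `significant`, `reason` (`NA` unless
#'   the correlation is undefined in that bin).
#' @export
within_bin_correlation <- function(binned, x_trait = "start_logg",
                                   y_trait = "dw", alpha = 0.05) {
  require_columns(binned, c("bin_lo", "bin_hi", x_trait, y_trait),
                  "binned")
  if (nrow(binned) == 0) {
    return(tibble::tibble(
      bin_lo = numeric(0), bin_hi = numeric(0), n = integer(0),
      x_trait = character(0), y_trait = character(0), r = numeric(0),
      p = numeric(0), significant = logical(0), reason = character(0)
    ))
  }
  binned |>
    dplyr::group_by(.data$bin_lo, .data$bin_hi) |>
    dplyr::group_modify(function(df, key) {
      x <- df[[x_trait]]; y <- df[[y_trait]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      row <- tibble::tibble(n = n, x_trait = x_trait, y_trait = y_trait,
                            r = NA_real_, p = NA_real_,
                            significant = NA, reason = NA_character_)
      if (n < 3) {
        row$reason <- "too_few_pairs"
      } else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        row$reason <- "zero_variance"
      } else {
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        row$r <- unname(ct$estimate)
        row$p <- ct$p.value
        row$significant <- row$p < alpha
      }
      row
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bin_lo)
}

#' Composite rate-and-duration traits
#'
#' Appends the two composite traits that probe the rate-duration
#' tradeoff: the ratio `max_gr / duration` and the sum of the ascending
#' ranks of the two traits (average ranks on ties). A plant ranks high on
#' the rank sum when it is both fast and long-growing. Rows with
#' non-positive duration are excluded with a warning.
#'
#' @param data Trait table with `max_gr` and `duration` columns.
#' @return The table with `ratio_maxgr_duration` and
#'   `rank_sum_maxgr_duration` appended.
#' @examples
#' composite_traits(tibble::tibble(max_gr = c(2, 1), duration = c(50, 100)))
#' @export
composite_traits <- function(data) {
  require_columns(data, c("max_gr", "duration"), "data")
  bad <- !is.na(data$duration) & data$duration <= 0
  if (any(bad)) {
    warn(paste0("Excluding ", sum(bad),
                " row(s) with non-positive duration."))
    data <- data[!bad, , drop = FALSE]
  }
  dplyr::mutate(
    dplyr::as_tibble(data),
    ratio_maxgr_duration = .data$max_gr / .data$duration,
    rank_sum_maxgr_duration = rank(.data$max_gr, ties.method = "average") +
      rank(.data$duration, ties.method = "average")
  )
}

#' Species representation in the extreme trait tails
#'
#' For each trait, the plants in the highest and lowest `fraction` of the
#' ranked population are identified and each species' share of that tail
#' is expressed as a percentage of that species' own members — an
#' extremes table adjusted for the unequal species group sizes in the
#' trial. The tail size is `k = round(fraction * N)` (half-up, minimum 1);
#' ties at the tail boundary are broken by stable rank order (first
#' occurrence in the table wins).
#'
#' @param data Trait table with a `species_group` column.
#' @param traits Character vector of trait columns (composite traits
#'   included where present).
#' @param fraction Tail fraction in `(0, 0.5)` (default 0.05).
#' @return A tibble with `species_group`, `trait`, `tail` (`"high"` or
#'   `"low"`), `n_in_tail`, `n_species`, `percent`. For each trait and
#'   tail the `n_in_tail` values sum to `k`.
#' @export
extremes_table <- function(data, traits, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5) {
    abort("`fraction` must lie strictly between 0 and 0.5.",
          class = "stemseason_domain_error")
  }
  require_columns(data, c("species_group", traits), "data")
  species <- sort(unique(data$species_group))
  species_sizes <- as.integer(table(data$species_group)[species])
  purrr::map_dfr(traits, function(tr) {
    vals <- data[[tr]]
    ok <- which(is.finite(vals))
    n <- length(ok)
    k <- max(1L, floor(fraction * n + 0.5))
    purrr::map_dfr(c("high", "low"), function(tail) {
      ord <- if (tail == "high") ok[order(-vals[ok])] else
        ok[order(vals[ok])]
      tail_idx <- ord[seq_len(min(k, n))]
      counts <- table(factor(data$species_group[tail_idx],
                             levels = species))
      tibble::tibble(
        species_group = species,
        trait = tr,
        tail = tail,
        n_in_tail = as.integer(counts),
        n_species = species_sizes,
        percent = 100 * as.integer(counts) / species_sizes
      )
    })
  })
}

#' Regression of early-growth timing on collection-site coordinates
#'
#' Fits one simple linear regression of the response (typically the day
#' of year, or accumulated degree days, at 15 cm stem height) on each
#' geographic predictor — latitude, longitude, altitude and altitude
#' squared — plus, optionally, a two-term model in latitude and altitude
#' squared. The most significant predictor (smallest p, ties by larger
#' adjusted R-squared) is flagged; if no model reaches `alpha` the
#' selection is `"none"`. Rows without coordinates are excluded.
#'
#' @param data Trait table with the response and coordinate columns.
#' @param response Name of the response column (e.g. `"day_at_15cm"`).
#' @param lat,lon,alt Names of the coordinate columns.
#' @param include_lat_alt2 Also fit the two-term `lat + alt^2` model
#'   (default `TRUE`); its p-value is the model F-test.
#' @param alpha Selection significance level (default 0.05).
#' @return A tibble with one row per model: `response`, `predictor`,
#'   `slope` (the latitude slope for the two-term model), `adj_r2`, `p`,
#'   `n`, `selected`. The name of the selected predictor (or `"none"`) is
#'   attached as attribute `"selected"`.
#' @export
geographic_regression <- function(data, response = "day_at_15cm",
                                  lat = "lat", lon = "lon", alt = "alt_m",
                                  include_lat_alt2 = TRUE, alpha = 0.05) {
  require_columns(data, c(response, lat, lon, alt), "data")
  df <- data.frame(
    y = data[[response]], lat = data[[lat]], lon = data[[lon]],
    alt = data[[alt]]
  )
  df <- df[stats::complete.cases(df), ]
  df$alt2 <- df$alt^2

  fit_one <- function(pred) {
    xv <- df[[pred]]
    if (length(unique(xv)) < 3) {
      return(tibble::tibble(predictor = pred, slope = NA_real_,
                            adj_r2 = NA_real_, p = NA_real_,
                            n = nrow(df)))
    }
    m <- lm(df$y ~ xv)
    s <- summary(m)
    tibble::tibble(
      predictor = pred,
      slope = unname(coef(m)[2]),
      adj_r2 = s$adj.r.squared,
      p = unname(s$coefficients[2, 4]),
      n = nrow(df)
    )
  }
  out <- purrr::map_dfr(c("lat", "lon", "alt", "alt2"), fit_one)
  if (include_lat_alt2 &&
      length(unique(df$lat)) >= 3 && length(unique(df$alt2)) >= 3) {
    m <- lm(y ~ lat + alt2, data = df)
    s <- summary(m)
    fstat <- s$fstatistic
    out <- dplyr::bind_rows(out, tibble::tibble(
      predictor = "lat_alt2",
      slope = unname(coef(m)["lat"]),
      adj_r2 = s$adj.r.squared,
      p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
      n = nrow(df)
    ))
  }
  out <- dplyr::mutate(out, response = response, .before = 1)
  est <- which(!is.na(out$p))
  if (length(est) > 0 && min(out$p[est]) < alpha) {
    best <- est[order(out$p[est], -out$adj_r2[est])][1]
    out$selected <- seq_len(nrow(out)) == best
    attr(out, "selected") <- out$predictor[best]
  } else {
    out$selected <- FALSE
    attr(out, "selected") <- "none"
  }
  out
}
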