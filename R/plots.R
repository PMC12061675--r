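#' Plot a fitted Richards curve over its data
#'
#' @param object A `richards_fit` from [fit_richards_one()].
#' @param ... Unused.
#' @return A ggplot: observed stem lengths and, for converged fits, the
#'   fitted curve with the logarithmic growth phase shaded and the day of
#'   maximum growth rate marked.
#' @method autoplot richards_fit
#' @export
autoplot.richards_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = "Day of year", y = "Stem length (cm)")
  if (object$converged) {
    pr <- object$params
    grid <- data.frame(x = seq(min(dat$x), max(dat$x), length.out = 200))
    grid$y <- richards_value(grid$x, pr[["a"]], pr[["b"]], pr[["c"]],
                             pr[["d"]])
    ch <- richards_characteristics(pr[["a"]], pr[["b"]], pr[["c"]],
                                   pr[["d"]])
    p <- p +
      ggplot2::annotate("rect", xmin = ch$start_logg, xmax = ch$end_logg,
                        ymin = -Inf, ymax = Inf, alpha = 0.12) +
      ggplot2::geom_line(data = grid) +
      ggplot2::geom_vline(xintercept = ch$day_max_gr, linetype = 2)
  }
  p
}

#' Plot within-bin correlations against duration bin
#'
#' One point per duration bin; filled points are significant at the
#' level used in [within_bin_correlation()], open points are not.
#'
#' @param binned_cor Tibble from [within_bin_correlation()].
#' @return A ggplot.
#' @export
plot_binned_correlations <- function(binned_cor) {
  d <- dplyr::filter(binned_cor, !is.na(.data$r))
  d$mid <- (d$bin_lo + d$bin_hi) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white")) +
    ggplot2::labs(
      x = "Duration bin midpoint (d)",
      y = paste0("r(", d$x_trait[1], ", ", d$y_trait[1], ")")
    )
}

#' Plot per-trait heritability estimates
#'
#' @param herit Tibble from [heritability()].
#' @return A ggplot bar chart of H-squared by trait.
#' @export
plot_heritability <- function(herit) {
  ggplot2::ggplot(herit,
                  ggplot2::aes(x = stats::reorder(.data$trait, -.data$h2),
                               y = .data$h2)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(H^2))
}
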