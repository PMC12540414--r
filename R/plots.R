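#' Forest-style plot of the strongest consensus signals
#'
#' RORs with 95% confidence intervals on a log scale, one row per PT,
#' ranked by ROR — the conventional presentation of a top-signal list.
#'
#' @param signals Output of [signal_table()].
#' @param top_n Number of signal PTs shown.
#' @param signals_only Restrict to consensus-flagged PTs.
#' @return A ggplot object.
#' @export
plot_signals <- function(signals, top_n = 30, signals_only = TRUE) {
  df <- signals
  if (signals_only) df <- df[df$is_signal, ]
  df <- df[!is.na(df$ror), ]
  df <- utils::head(df[order(-df$ror), ], top_n)
  df$pt <- factor(df$pt, levels = rev(df$pt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$pt)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(size = .data$a), shape = 18) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
                  size = "cases") +
    ggplot2::theme_minimal()
}

#' Step plot of a Kaplan-Meier onset curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object showing cumulative incidence (1 - survival).
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(time = c(0, object$time),
                       cuminc = c(0, 1 - object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cuminc)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days since therapy start",
                  y = "Cumulative incidence of reported events") +
    ggplot2::theme_minimal()
}

#' Onset-time histogram with the fitted Weibull density
#'
#' @param object A `weibull_fit`.
#' @param records The onset records the fit was computed from (tibble
#'   with `days`, or numeric vector).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weibull_fit
#' @export
autoplot.weibull_fit <- function(object, records, ...) {
  t <- if (is.numeric(records)) records else records$days
  df <- tibble::tibble(days = t)
  grid <- tibble::tibble(
    days = seq(min(t), max(t), length.out = 400),
    dens = stats::dweibull(seq(min(t), max(t), length.out = 400),
                           shape = object$shape, scale = object$scale))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$days, y = .data$dens),
                       linewidth = 0.8) +
    ggplot2::labs(x = "Days to onset", y = "Density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
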