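# ggplot2 visualizations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Sloan neutral-model fit
#'
#' The classic occurrence-frequency versus log mean-relative-abundance
#' scatter, with the fitted neutral prediction curve and its Wilson
#' confidence envelope; points are coloured by their position relative to
#' the envelope.
#'
#' @param object An `"ncm_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ncm_fit
#' @export
autoplot.ncm_fit <- function(object, ...) {
  taxa <- dplyr::arrange(object$taxa, .data$p)
  ggplot2::ggplot(taxa, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_freq, colour = .data$position),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Mean relative abundance",
      y = "Occurrence frequency",
      colour = "Position",
      title = sprintf("Sloan NCM fit: Nm = %.3g, R² = %.3f",
                      object$Nm, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an octave histogram with optional fitted SAD curves
#'
#' @param hist An [octave_histogram()].
#' @param fits Optional list of `"sad_fit"` objects to overlay.
#' @return A ggplot.
#' @export
plot_octaves <- function(hist, fits = NULL) {
  g <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$octave, y = .data$n_species)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "Octave (log2 abundance class)", y = "Species") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    curves <- dplyr::bind_rows(purrr::map(fits, tidy))
    g <- g + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$octave, y = .data$expected, colour = .data$model)
    ) + ggplot2::labs(colour = "Model")
  }
  g
}

#' Plot per-sample beta-null deviations by cohort
#'
#' @param object A `"null_deviation"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_deviation
#' @export
autoplot.null_deviation <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$cohort, y = .data$mean_deviation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Beta-null deviation (per-sample mean)") +
    ggplot2::theme_minimal()
}

#' Plot a time-decay fit
#'
#' @param object A `"time_decay_fit"`.
#' @param ... Unused.
#' @return A ggplot (log-log axes; dropped pairs shown hollow).
#' @method autoplot time_decay_fit
#' @export
autoplot.time_decay_fit <- function(object, ...) {
  used <- dplyr::filter(object$pairs, .data$used)
  ggplot2::ggplot(used, ggplot2::aes(x = .data$lag_days, y = .data$similarity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time lag (days)", y = "Community similarity (1 - Bray-Curtis)",
      title = sprintf("Time-decay: slope = %.3g, p = %.3g",
                      object$slope, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the neutrality fraction against abundance
#'
#' @param object A `"neutrality_curve"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot neutrality_curve
#' @export
autoplot.neutrality_curve <- function(object, ...) {
  bins <- dplyr::mutate(object$bins, p_mid = sqrt(.data$p_lo * .data$p_hi))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$p_mid, y = .data$neutrality_fraction)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean relative abundance (bin midpoint)",
                  y = "Neutrality fraction", size = "Taxa") +
    ggplot2::theme_minimal()
}
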