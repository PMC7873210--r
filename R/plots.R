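#' Plot the RMSPE profile of a contact-energy fit
#'
#' Profile of the objective over the scanned contact energies with the best
#' fit marked and the +/- band shaded.
#'
#' @param object A `dgcon_fit`.
#' @param band_offset Half-width of the shaded band, kcal/mol.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dgcon_fit <- function(object, band_offset = 0.25, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$dg_con, y = .data$rmspe)) +
    ggplot2::annotate("rect",
                      xmin = object$dg_best - band_offset,
                      xmax = object$dg_best + band_offset,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$dg_best, linetype = "dashed") +
    ggplot2::labs(x = "|dG_con| (kcal/mol)", y = "RMSPE (%)",
                  title = sprintf("Best fit |dG_con| = %.2f kcal/mol",
                                  object$dg_best)) +
    ggplot2::theme_minimal()
}

#' Plot a Hill analysis
#'
#' Logit assembly efficiency against log free-component concentration with
#' the regression line; the slope is the Hill coefficient and the x-intercept
#' the log apparent KD.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log_l, y = .data$logit_theta)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$hill_coefficient,
                         intercept = unname(coef(object$lm)[1]),
                         linetype = "dashed") +
    ggplot2::labs(x = "log10 [free components] (uM)",
                  y = "log10 (theta / (1 - theta))",
                  title = sprintf("Hill coefficient %.1f, apparent KD %.1f uM",
                                  object$hill_coefficient,
                                  object$apparent_kd_uM)) +
    ggplot2::theme_minimal()
}

#' Chevron plot of a cooperativity dataset
#'
#' Normalized high- and low-MW signals against the variable component
#' concentration, one panel per series, with replicate error bars and the
#' theoretical-yield reference line.
#'
#' @param chevron A [chevron_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_chevron <- function(chevron) {
  long <- tidyr::pivot_longer(
    chevron,
    cols = c("high_mean", "low_mean"),
    names_to = "fraction", values_to = "signal")
  long$sd <- ifelse(long$fraction == "high_mean", chevron$high_sd[
    match(interaction(long$series_id, long$variable_uM),
          interaction(chevron$series_id, chevron$variable_uM))],
    chevron$low_sd[match(interaction(long$series_id, long$variable_uM),
                         interaction(chevron$series_id, chevron$variable_uM))])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable_uM, y = .data$signal,
                                     colour = .data$fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theoretical_yield),
                       colour = "grey60", linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$signal - .data$sd,
                                          ymax = .data$signal + .data$sd)) +
    ggplot2::facet_wrap(~series_id) +
    ggplot2::labs(x = "[variable component] (uM)",
                  y = "normalized peak area",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot assembled mass fraction against total input concentration
#'
#' Convenience view of an equilibrium table solved over an equimolar series:
#' the sigmoidal mass-fraction curve across the pseudo-critical transition.
#'
#' @param object An equilibrium tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equilibrium_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t0_uM + .data$p0_uM,
                               y = .data$mass_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total input monomer (uM)",
                  y = "assembled mass fraction") +
    ggplot2::theme_minimal()
}
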