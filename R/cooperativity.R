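#' Assembled mass fraction from normalized peak areas
#'
#' For equimolar assembly reactions, converts normalized high/low-MW peak
#' signals into the assembled mass fraction and molar monomer amounts. The
#' low-MW signal is first un-adjusted (divided by the A280 adjustment factor)
#' so both fractions are on the same concentration scale; the molar split
#' assumes equimolar stoichiometry in both the assembled and the residual
#' fractions.
#'
#' @param records A normalized peak-area tibble (columns `t0_uM`, `p0_uM`,
#'   `high_norm`, `low_norm`).
#' @param factors A [signal_factors()] object supplying the adjustment factor.
#' @return `records` with columns `theta` (assembled mass fraction),
#'   `assembled_uM` and `free_uM` (monomer equivalents) added.
#' @examples
#' rec <- tibble::tibble(t0_uM = 50, p0_uM = 50,
#'                       high_norm = 0.5, low_norm = 0.445)
#' mass_fraction_from_peaks(rec, signal_factors(0.89))  # theta = 0.5
#' @export
mass_fraction_from_peaks <- function(records, factors = signal_factors()) {
  needed <- c("t0_uM", "p0_uM", "high_norm", "low_norm")
  if (!all(needed %in% names(records))) {
    abort("`records` must carry t0_uM, p0_uM, high_norm, low_norm.")
  }
  low_adj <- records$low_norm / factors$f_a280
  tot_sig <- records$high_norm + low_adj
  if (any(tot_sig == 0)) abort("Zero total signal; mass fraction undefined.")
  dplyr::mutate(records,
                theta = records$high_norm / tot_sig,
                assembled_uM = .data$theta * (.data$t0_uM + .data$p0_uM),
                free_uM = (1 - .data$theta) * (.data$t0_uM + .data$p0_uM))
}

#' Hill analysis of an equimolar assembly series
#'
#' Regresses `log10(theta / (1 - theta))` on `log10(L)`, where `theta` is the
#' assembled mass fraction and `L` the residual free component concentration
#' (total unassembled monomer, uM). The slope is the Hill coefficient; the
#' x-intercept, back-transformed, is the apparent dissociation constant of
#' assembly. Replicates are averaged per concentration before regression, and
#' only points with `theta` strictly inside `theta_band` enter the fit (near
#' 0 or 1 the logit is dominated by measurement noise).
#'
#' @param records Either a normalized equimolar peak-area tibble (routed
#'   through [mass_fraction_from_peaks()]) or a tibble that already has
#'   `theta` and `free_uM` columns.
#' @param factors [signal_factors()] used when `theta` must be computed.
#' @param theta_band Inclusion band for `theta`, default (0.05, 0.95).
#' @return An object of class `hill_fit`: list with `hill_coefficient`,
#'   `apparent_kd_uM`, `r_squared`, `points` (the regression table),
#'   `n_points`, `theta_range`, and the underlying `lm` fit. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' # exact Hill law: theta/(1-theta) = (L/10)^3
#' L <- c(5, 8, 12, 20)
#' th <- (L / 10)^3 / (1 + (L / 10)^3)
#' hill_analysis(tibble::tibble(theta = th, free_uM = L))
#' @export
hill_analysis <- function(records, factors = signal_factors(),
                          theta_band = c(0.05, 0.95)) {
  stopifnot(length(theta_band) == 2L, theta_band[1] < theta_band[2])
  if (!all(c("theta", "free_uM") %in% names(records))) {
    records <- mass_fraction_from_peaks(records, factors)
  }
  pts <- if ("t0_uM" %in% names(records)) {
    dplyr::summarise(
      dplyr::group_by(records, .data$t0_uM, .data$p0_uM),
      theta = mean(.data$theta), free_uM = mean(.data$free_uM),
      .groups = "drop")
  } else {
    dplyr::summarise(
      dplyr::group_by(records, .data$free_uM),
      theta = mean(.data$theta), .groups = "drop")
  }
  usable <- pts$theta > theta_band[1] & pts$theta < theta_band[2] &
    pts$free_uM > 0
  pts <- pts[usable, ]
  if (nrow(pts) < 2L) {
    abort(sprintf(
      "Hill analysis needs >= 2 points with theta in (%.2f, %.2f); %d available.",
      theta_band[1], theta_band[2], nrow(pts)))
  }
  pts <- dplyr::mutate(pts,
                       log_l = log10(.data$free_uM),
                       logit_theta = log10(.data$theta / (1 - .data$theta)))
  fit <- lm(logit_theta ~ log_l, data = pts)
  slope <- unname(coef(fit)[["log_l"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  ss_tot <- sum((pts$logit_theta - mean(pts$logit_theta))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(hill_coefficient = slope,
         apparent_kd_uM = 10^(-intercept / slope),
         r_squared = r2,
         points = pts, n_points = nrow(pts),
         theta_range = range(pts$theta), lm = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> Hill coefficient %.2f, apparent KD %.2f uM (R^2 %.4f, %d points)\n",
    x$hill_coefficient, x$apparent_kd_uM, x$r_squared, x$n_points))
  invisible(x)
}

#' Chevron summary of a cooperativity dataset
#'
#' For assembly series in which one component is held constant and the other
#' varied, summarizes the normalized high- and low-MW signals per variable
#' concentration (replicate mean and propagated standard deviation) together
#' with the theoretical-yield reference line assuming quantitative
#' incorporation of the limiting component. Plotted against the variable
#' concentration, the residual-component signal of a cooperative system traces
#' a V (chevron) with its minimum at the equimolar point.
#'
#' The propagated sd combines the replicate scatter of each point with the
#' scatter of the normalization reference recorded by
#' [normalize_peak_areas()] via [propagate_sd()].
#'
#' @param records A normalized peak-area tibble carrying `series_id` values
#'   `"vary_t"` / `"vary_p"` (or any series labels), replicate structure, and
#'   the normalization attributes.
#' @param extinctions Extinction coefficients used for the theoretical-yield
#'   line.
#' @param factors [signal_factors()] (reference concentrations).
#' @return A tibble with one row per (series, variable concentration):
#'   `series_id`, `variable_uM`, `t0_uM`, `p0_uM`, `high_mean`, `high_sd`,
#'   `low_mean`, `low_sd`, `n_replicates`, `theoretical_yield`.
#' @export
chevron_summary <- function(records, extinctions = default_components(),
                            factors = signal_factors()) {
  needed <- c("series_id", "t0_uM", "p0_uM", "high_norm", "low_norm")
  if (!all(needed %in% names(records))) {
    abort("`records` must be normalized and carry a series_id column.")
  }
  if ("is_reference" %in% names(records)) {
    records <- records[!records$is_reference, ]
  }
  ext <- extinction_pair(extinctions)
  ref_high <- attr(records, "ref_high")
  ref_low <- attr(records, "ref_low")
  rel_ref_high <- if (!is.null(ref_high) && ref_high[["mean"]] > 0) {
    ref_high[["sd"]] / ref_high[["mean"]]
  } else 0
  rel_ref_low <- if (!is.null(ref_low) && ref_low[["mean"]] > 0) {
    ref_low[["sd"]] / ref_low[["mean"]]
  } else 0
  denom <- factors$reference_t0 * ext[["t"]] + factors$reference_p0 * ext[["p"]]

  sd_or_0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$series_id, .data$t0_uM, .data$p0_uM),
    high_mean = mean(.data$high_norm),
    high_repl_sd = sd_or_0(.data$high_norm),
    low_mean = mean(.data$low_norm),
    low_repl_sd = sd_or_0(.data$low_norm),
    n_replicates = dplyr::n(),
    .groups = "drop")
  out <- dplyr::mutate(
    out,
    variable_uM = dplyr::if_else(grepl("t$", .data$series_id), .data$t0_uM, .data$p0_uM),
    high_sd = ifelse(
      .data$high_mean == 0, 0,
      abs(.data$high_mean) * sqrt((.data$high_repl_sd / ifelse(.data$high_mean == 0, 1, .data$high_mean))^2 +
                                    rel_ref_high^2)),
    low_sd = ifelse(
      .data$low_mean == 0, 0,
      abs(.data$low_mean) * sqrt((.data$low_repl_sd / ifelse(.data$low_mean == 0, 1, .data$low_mean))^2 +
                                   rel_ref_low^2)),
    theoretical_yield = (pmin(.data$t0_uM, .data$p0_uM) * ext[["t"]] +
                           pmin(.data$t0_uM, .data$p0_uM) * ext[["p"]]) / denom)
  dplyr::select(out, "series_id", "variable_uM", "t0_uM", "p0_uM",
                "high_mean", "high_sd", "low_mean", "low_sd",
                "n_replicates", "theoretical_yield")
}
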