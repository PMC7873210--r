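#' Construct a melt curve
#'
#' A temperature-indexed signal trace from a thermal ramp: circular dichroism
#' mean residue ellipticity (`cd_mre`), intrinsic-fluorescence barycentric
#' mean (`nanodsf_bcm`), static light scattering counts (`sls_counts`), or
#' residual enzymatic activity (`activity`).
#'
#' @param temperature_C Strictly increasing temperatures, degrees C.
#' @param signal Signal values, same length (>= 4), no missing values.
#' @param assay Assay type (see above).
#' @param sample Optional sample label.
#' @param ratio Optional input \[T\]0:\[P\]0 ratio annotation.
#' @return A tibble with columns `temperature_C`, `signal` and attributes
#'   `assay`, `sample`, `ratio`.
#' @export
melt_curve <- function(temperature_C, signal,
                       assay = c("cd_mre", "nanodsf_bcm", "sls_counts",
                                 "activity"),
                       sample = NA_character_, ratio = NA_character_) {
  assay <- match.arg(assay)
  if (length(temperature_C) != length(signal) || length(signal) < 4L) {
    abort("Melt curves need >= 4 paired (temperature, signal) points.")
  }
  if (any(diff(temperature_C) <= 0)) {
    abort("Temperatures must be strictly increasing.")
  }
  if (anyNA(temperature_C) || anyNA(signal)) abort("Missing values are not allowed.")
  out <- tibble::tibble(temperature_C = temperature_C, signal = signal)
  attr(out, "assay") <- assay
  attr(out, "sample") <- sample
  attr(out, "ratio") <- ratio
  out
}

# piecewise local quadratic interpolation (3 nearest samples per query)
quad_interp <- function(x, y, xout) {
  n <- length(x)
  i <- findInterval(xout, x, all.inside = TRUE)  # xout in [x[i], x[i+1]]
  i0 <- pmin(pmax(i - 1L, 1L), n - 2L)           # leftmost of 3-point stencil
  x1 <- x[i0]; x2 <- x[i0 + 1L]; x3 <- x[i0 + 2L]
  y1 <- y[i0]; y2 <- y[i0 + 1L]; y3 <- y[i0 + 2L]
  l1 <- (xout - x2) * (xout - x3) / ((x1 - x2) * (x1 - x3))
  l2 <- (xout - x1) * (xout - x3) / ((x2 - x1) * (x2 - x3))
  l3 <- (xout - x1) * (xout - x2) / ((x3 - x1) * (x3 - x2))
  y1 * l1 + y2 * l2 + y3 * l3
}

#' Melting temperature by the derivative method
#'
#' Interpolates the trace onto a fine temperature grid with a local quadratic
#' interpolant, differentiates by central differences, and reports the
#' temperature of the derivative extremum in the direction of the overall
#' transition. Appropriate for sigmoidal unfolding signals (CD ellipticity,
#' residual activity). The caller is invariant to affine rescaling of the
#' signal; traces without a discernible transition (derivative peak
#' indistinct from the baseline slope) are an error.
#'
#' @param curve A [melt_curve()] (or tibble with `temperature_C`, `signal`).
#' @param grid_step Interpolation grid spacing, degrees C.
#' @param peak_ratio Minimum ratio of the peak derivative to the median
#'   derivative magnitude for a transition to be called.
#' @return Tm in degrees C.
#' @examples
#' tm_by_derivative(sim_melt_curve(tm = 70, seed = 1, noise_sd = 0))
#' @export
tm_by_derivative <- function(curve, grid_step = 0.1, peak_ratio = 2) {
  tt <- curve$temperature_C
  ss <- curve$signal
  if (length(tt) < 4L) abort("Need >= 4 points.")
  grid <- seq(tt[1], tt[length(tt)], by = grid_step)
  sg <- quad_interp(tt, ss, grid)
  d <- c(NA, (sg[-(1:2)] - sg[1:(length(sg) - 2)]) / (2 * grid_step), NA)
  direction <- sign(ss[length(ss)] - ss[1])
  if (direction == 0) abort("No transition: flat trace.")
  dd <- d * direction
  inner <- 2:(length(grid) - 1L)
  peak <- max(dd[inner])
  med <- median(abs(dd[inner]))
  if (peak <= 0 || (med > 0 && peak / med < peak_ratio)) {
    abort("No transition detected (derivative peak indistinct from baseline).")
  }
  grid[inner][which.max(dd[inner])]
}

#' Threshold specification for onset calling
#'
#' Defines the threshold line used by [t_by_threshold()]: slope equal to the
#' average baseline drift of the dataset and intercept (at the starting
#' temperature) equal to a stated fraction of a typical endpoint magnitude.
#' Presets encode the assay conventions of the reference analyses:
#' \describe{
#'   \item{`sls`}{20% of a 60,000-count endpoint over background.}
#'   \item{`nanodsf_i53_40`}{50% of the -4.5 nm BCM shift at 95 C.}
#'   \item{`nanodsf_i53_50`}{20% of the -14.2 nm BCM shift of the pentamer.}
#'   \item{`cd_i53_50`}{20% of the expected ellipticity loss on pentamer
#'     denaturation; the magnitude is system-specific and must be supplied
#'     via `endpoint_magnitude`.}
#' }
#'
#' @param preset Optional preset name (above).
#' @param intercept_fraction Fraction in (0, 1\] of the endpoint magnitude.
#' @param endpoint_magnitude Assay endpoint magnitude (signed, signal units).
#' @param drift_slope Baseline drift, signal units per degree C (see
#'   [baseline_drift()]).
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(preset = NULL, intercept_fraction = NULL,
                           endpoint_magnitude = NULL, drift_slope = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("sls", "nanodsf_i53_40", "nanodsf_i53_50",
                                  "cd_i53_50"))
    defaults <- switch(preset,
      sls = list(frac = 0.2, endpoint = 60000),
      nanodsf_i53_40 = list(frac = 0.5, endpoint = -4.5),
      nanodsf_i53_50 = list(frac = 0.2, endpoint = -14.2),
      cd_i53_50 = list(frac = 0.2, endpoint = NULL))
    intercept_fraction <- intercept_fraction %||% defaults$frac
    endpoint_magnitude <- endpoint_magnitude %||% defaults$endpoint
  }
  if (is.null(intercept_fraction) || is.null(endpoint_magnitude)) {
    abort("Both `intercept_fraction` and `endpoint_magnitude` are required (the cd_i53_50 preset needs an explicit endpoint).")
  }
  stopifnot(intercept_fraction > 0, intercept_fraction <= 1)
  structure(list(preset = preset %||% "custom",
                 intercept_fraction = intercept_fraction,
                 endpoint_magnitude = endpoint_magnitude,
                 drift_slope = drift_slope),
            class = "threshold_spec")
}

#' Pooled baseline drift of a set of melt curves
#'
#' Average initial-region slope across curves of one assay, used as the slope
#' of the threshold line. Pooling is per assay by default (each curve
#' contributes one least-squares slope over its first `n_baseline` points);
#' pass a single curve for a per-curve drift.
#'
#' @param curves A list of melt curves (or a single curve).
#' @param n_baseline Number of leading points defining the baseline region.
#' @return Average drift slope, signal units per degree C.
#' @export
baseline_drift <- function(curves, n_baseline = 10) {
  if (is.data.frame(curves)) curves <- list(curves)
  slopes <- purrr::map_dbl(curves, function(cv) {
    k <- min(n_baseline, nrow(cv))
    if (k < 2L) return(0)
    unname(coef(lm(signal ~ temperature_C, data = cv[seq_len(k), ]))[2L])
  })
  mean(slopes)
}

#' Onset temperature by threshold crossing
#'
#' Builds the threshold line `intercept_fraction * endpoint_magnitude +
#' drift_slope * (T - T_start)` relative to the starting signal, interpolates
#' the trace with a cubic spline onto a fine grid, and reports the first
#' temperature at which the trace crosses the line (onset semantics: the
#' lowest crossing is returned when several exist). Used for aggregation
#' onset from SLS counts and for melting onset from BCM / CD traces where the
#' transition has no clean inflection.
#'
#' @param curve A [melt_curve()].
#' @param spec A [threshold_spec()].
#' @param grid_step Interpolation grid spacing, degrees C.
#' @return Crossing temperature in degrees C.
#' @examples
#' sls <- sim_melt_curve(tm = 80, assay = "sls_counts", amplitude = 60000,
#'                       noise_sd = 0, seed = 1)
#' t_by_threshold(sls, threshold_spec("sls"))
#' @export
t_by_threshold <- function(curve, spec, grid_step = 0.1) {
  stopifnot(inherits(spec, "threshold_spec"))
  tt <- curve$temperature_C
  ss <- curve$signal
  sf <- stats::splinefun(tt, ss, method = "fmm")
  grid <- seq(tt[1], tt[length(tt)], by = grid_step)
  line <- ss[1] + spec$intercept_fraction * spec$endpoint_magnitude +
    spec$drift_slope * (grid - tt[1])
  diffsig <- sf(grid) - line
  s0 <- sign(diffsig[1])
  # first sign change relative to the starting side
  idx <- which(sign(diffsig) != s0 & sign(diffsig) != 0)
  if (!length(idx)) {
    abort("Trace never crosses the threshold line within the scanned range.")
  }
  i <- idx[1]
  # linear refinement between grid points
  x1 <- grid[i - 1L]; x2 <- grid[i]
  y1 <- diffsig[i - 1L]; y2 <- diffsig[i]
  x1 + (0 - y1) * (x2 - x1) / (y2 - y1)
}

#' Initial reaction velocity from a kinetic absorbance trace
#'
#' Ordinary least-squares slope of absorbance vs. time over a stated window
#' (100-200 s by default, matching the coupled aldolase assay readout), with
#' optional normalization to a control slope to yield relative residual
#' activity.
#'
#' @param trace A data frame with columns `time_s` and `a339` (or any
#'   absorbance column named in `signal_col`).
#' @param window Two-element numeric, seconds.
#' @param control_slope Optional control (untreated) slope; when given, the
#'   result is `slope / control_slope`.
#' @param signal_col Name of the absorbance column.
#' @return A list with `slope` (absorbance per second) and `relative`
#'   (NULL unless a control slope is supplied).
#' @examples
#' tr <- tibble::tibble(time_s = 0:300, a339 = 1 - 0.001 * (0:300))
#' initial_rate(tr)$slope  # -0.001
#' @export
initial_rate <- function(trace, window = c(100, 200), control_slope = NULL,
                         signal_col = "a339") {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(keep) < 3L) abort("Fewer than 3 trace points in the rate window.")
  d <- data.frame(t = trace$time_s[keep], y = trace[[signal_col]][keep])
  slope <- unname(coef(lm(y ~ t, data = d))[2L])
  rel <- if (!is.null(control_slope)) {
    if (control_slope == 0) abort("Control slope is zero.")
    slope / control_slope
  } else NULL
  list(slope = slope, relative = rel)
}
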