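#' Slice a forward-model grid onto a 2D plane and bin it
#'
#' The forward parameterization produces surfaces over (\[T\]0, \[P\]0). For
#' comparison with a 2D data series the surface is cut to a thin slab around
#' the plane of interest (the equimolar plane, or a constant-component plane)
#' and the retained points are averaged within bins of the in-plane
#' coordinate. Points farther than `slab_width / 2` from the plane (measured
#' as the difference of the two totals, or of the constant total from its
#' target) are dropped.
#'
#' @param grid An equilibrium tibble from [forward_grid()] (optionally with
#'   signal columns from [predict_normalized_signals()]).
#' @param plane `"equimolar"`, `"constant_t"` or `"constant_p"`.
#' @param constant_value Target value (uM) of the constant component for the
#'   constant-component planes.
#' @param slab_width Slab thickness, uM.
#' @param bin_width Bin width of the in-plane coordinate, uM. The reference
#'   analyses used 0.5 uM (and 0.0625 uM for the steeper of the two systems
#'   on the equimolar plane).
#' @return A tibble with `bin` (bin-center coordinate, uM), `n_points`, and
#'   the mean of every numeric grid column within the bin. Empty bins are
#'   absent.
#' @export
slice_and_bin <- function(grid,
                          plane = c("equimolar", "constant_t", "constant_p"),
                          constant_value = 50, slab_width = 1,
                          bin_width = 0.5) {
  plane <- match.arg(plane)
  stopifnot(slab_width > 0, bin_width > 0, nrow(grid) > 0)
  off <- switch(plane,
    equimolar = abs(grid$t0_uM - grid$p0_uM),
    constant_t = abs(grid$t0_uM - constant_value),
    constant_p = abs(grid$p0_uM - constant_value))
  coord <- switch(plane,
    equimolar = (grid$t0_uM + grid$p0_uM) / 2,
    constant_t = grid$p0_uM,
    constant_p = grid$t0_uM)
  keep <- off <= slab_width / 2
  if (!any(keep)) abort("All grid points fall outside the slab.")
  kept <- dplyr::mutate(grid[keep, ],
                        bin = (floor(coord[keep] / bin_width) + 0.5) * bin_width)
  kept$converged <- NULL
  dplyr::summarise(
    dplyr::group_by(kept, .data$bin),
    n_points = dplyr::n(),
    dplyr::across(dplyr::where(is.numeric), mean),
    .groups = "drop")
}

#' Root mean squared percent error
#'
#' `sqrt(mean((100 * (theoretical - experimental) / experimental)^2))`, the
#' objective minimized when fitting the contact energy. The percent error is
#' asymmetric by construction (experimental value in the denominator); points
#' with a zero experimental value are excluded with a warning since their
#' percent error is undefined.
#'
#' @param theoretical,experimental Equal-length numeric vectors.
#' @return RMSPE in percent.
#' @examples
#' rmspe(c(110, 90), c(100, 100))  # 10
#' @export
rmspe <- function(theoretical, experimental) {
  stopifnot(length(theoretical) == length(experimental))
  bad <- experimental == 0
  if (any(bad)) {
    warn(sprintf("Excluding %d point(s) with zero experimental value from RMSPE.",
                 sum(bad)))
    theoretical <- theoretical[!bad]
    experimental <- experimental[!bad]
  }
  if (!length(theoretical)) abort("No usable points for RMSPE.")
  sqrt(mean((100 * (theoretical - experimental) / experimental)^2))
}

#' Fit the per-contact energy by RMSPE minimization
#'
#' Scans the contact-energy magnitude over a grid, predicts the normalized
#' high- and low-MW SEC signals at every experimental input-concentration
#' pair via the inverse equilibrium solver, and minimizes the pooled root
#' mean squared percent error over all retained observations. Replicates are
#' averaged per (t0, p0) before pooling. An optional restriction drops
#' concentration pairs before fitting (for systems that assemble aberrantly
#' when the pentamer is super-stoichiometric, only points with
#' \[T\]0 >= \[P\]0 are retained).
#'
#' The scan default (2.5 to 5.5 kcal/mol in 0.01 steps) brackets per-contact
#' energies reported for cooperatively assembling icosahedral architectures
#' and resolves the minimum an order of magnitude finer than the +/-0.25
#' kcal/mol visualization band.
#'
#' @param records A normalized peak-area tibble ([normalize_peak_areas()] or
#'   any tibble with `t0_uM`, `p0_uM`, `high_norm`, `low_norm`).
#' @param species [species_table()] used for prediction (inclusive by
#'   default).
#' @param extinctions,factors Signal model, as in
#'   [predict_normalized_signals()].
#' @param dg_scan Numeric vector of contact-energy magnitudes (kcal/mol).
#' @param restriction `NULL`, the string `"t0_ge_p0"`, or a predicate
#'   `function(t0, p0)` returning `TRUE` for points to keep.
#' @param use Which signals enter the objective: `"both"`, `"high"`, `"low"`.
#' @param temperature Absolute temperature, K.
#' @param band_offset Half-width (kcal/mol) of the model band stored for
#'   plotting, drawn at the best fit +/- this offset.
#' @return An object of class `dgcon_fit`: a list with `dg_best`, `rmspe_min`,
#'   `profile` (tibble of `dg_con`, `rmspe`), `predictions` (per-point model
#'   vs data at `dg_best`), `band` (predictions at `dg_best +/- band_offset`),
#'   `n_points`, `restriction`, `boundary` (TRUE if the minimum sits on the
#'   scan edge). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' dat <- sim_equimolar_series(3.6, totals = c(10, 25, 50, 100),
#'                             noise_cv = 0, seed = 1)
#' fit <- fit_dgcon(normalize_peak_areas(dat),
#'                  dg_scan = seq(3.3, 3.9, 0.05))
#' glance(fit)
#' }
#' @export
fit_dgcon <- function(records,
                      species = species_table("inclusive"),
                      extinctions = default_components(),
                      factors = signal_factors(),
                      dg_scan = seq(2.5, 5.5, by = 0.01),
                      restriction = NULL,
                      use = c("both", "high", "low"),
                      temperature = 296,
                      band_offset = 0.25) {
  use <- match.arg(use)
  needed <- c("t0_uM", "p0_uM", "high_norm", "low_norm")
  if (!all(needed %in% names(records))) {
    abort("`records` must carry normalized signals (t0_uM, p0_uM, high_norm, low_norm).")
  }
  stopifnot(length(dg_scan) >= 2L, all(diff(dg_scan) > 0))
  if ("is_reference" %in% names(records)) {
    # reference injections are calibration standards, not observations
    records <- records[!records$is_reference, ]
  }

  obs <- dplyr::summarise(
    dplyr::group_by(records, .data$t0_uM, .data$p0_uM),
    high_obs = mean(.data$high_norm),
    low_obs = mean(.data$low_norm),
    .groups = "drop")
  restriction_label <- "none"
  if (!is.null(restriction)) {
    if (identical(restriction, "t0_ge_p0")) {
      restriction_label <- "t0 >= p0"
      restriction <- function(t0, p0) t0 >= p0
    } else {
      restriction_label <- "custom"
    }
    obs <- obs[restriction(obs$t0_uM, obs$p0_uM), ]
  }
  if (nrow(obs) < 2L) abort("Fewer than 2 concentration points after restriction.")

  predict_at <- function(dg) {
    st <- solve_equilibrium(obs[, c("t0_uM", "p0_uM")],
                            thermo_params(dg, temperature), species)
    predict_normalized_signals(st, extinctions, factors)
  }
  objective <- function(pred) {
    theo <- switch(use,
      both = c(pred$high_signal, pred$low_signal),
      high = pred$high_signal,
      low = pred$low_signal)
    expd <- switch(use,
      both = c(obs$high_obs, obs$low_obs),
      high = obs$high_obs,
      low = obs$low_obs)
    keep <- expd != 0
    if (sum(keep) < length(expd)) {
      # zero observations carry no percent-error information; drop silently
      theo <- theo[keep]; expd <- expd[keep]
    }
    sqrt(mean((100 * (theo - expd) / expd)^2))
  }
  profile <- tibble::tibble(
    dg_con = dg_scan,
    rmspe = purrr::map_dbl(dg_scan, function(dg) objective(predict_at(dg))))
  i_best <- which.min(profile$rmspe)
  boundary <- i_best %in% c(1L, nrow(profile))
  if (boundary) {
    warn("RMSPE minimum lies on the scan boundary; widen `dg_scan`.")
  }
  if (diff(range(profile$rmspe)) < sqrt(.Machine$double.eps)) {
    warn("RMSPE profile is flat; the fit is degenerate.")
  }
  dg_best <- profile$dg_con[i_best]
  preds <- dplyr::bind_cols(obs, predict_at(dg_best)[, c("high_signal", "low_signal")])
  band <- purrr::map_dfr(
    c(lower = dg_best - band_offset, upper = dg_best + band_offset),
    function(dg) dplyr::mutate(
      predict_at(max(dg, 0))[, c("t0_uM", "p0_uM", "high_signal", "low_signal")],
      dg_con = max(dg, 0)),
    .id = "edge")
  structure(
    list(dg_best = dg_best, rmspe_min = profile$rmspe[i_best],
         profile = profile, predictions = preds, band = band,
         n_points = nrow(obs), use = use,
         restriction = restriction_label, boundary = boundary,
         dg_scan = range(dg_scan), factors = factors),
    class = "dgcon_fit")
}

#' @export
print.dgcon_fit <- function(x, ...) {
  cat(sprintf("<dgcon_fit> |dG_con| = %.2f kcal/mol (RMSPE %.2f%%, %d points, restriction: %s)\n",
              x$dg_best, x$rmspe_min, x$n_points, x$restriction))
  if (x$boundary) cat("  warning: minimum on scan boundary\n")
  invisible(x)
}
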