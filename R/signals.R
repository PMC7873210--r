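#' Signal adjustment factors for SEC peak-area normalization
#'
#' Assembled nanomaterial scatters measurably at 280 nm, producing ~10% more
#' apparent absorbance than the same material injected as separate components.
#' The adjustment factor `f_a280` (components-over-assembled summed-signal
#' ratio, about 0.89-0.90 for the reference systems) carries that systematic
#' difference through the analysis; it multiplies the model-predicted low-MW
#' signal so model and experiment share a scale.
#'
#' @param f_a280 Unitless adjustment factor, in (0, 1.2\].
#' @param f_a280_sd Its standard deviation across replicates.
#' @param reference_t0,reference_p0 Input concentrations (uM) of the equimolar
#'   reference assemblies used for normalization.
#' @return A list of class `signal_factors`.
#' @export
signal_factors <- function(f_a280 = 0.89, f_a280_sd = 0.06,
                           reference_t0 = 50, reference_p0 = 50) {
  stopifnot(f_a280 > 0, f_a280 <= 1.2, f_a280_sd >= 0,
            reference_t0 > 0, reference_p0 > 0)
  structure(list(f_a280 = f_a280, f_a280_sd = f_a280_sd,
                 reference_t0 = reference_t0, reference_p0 = reference_p0),
            class = "signal_factors")
}

#' @export
print.signal_factors <- function(x, ...) {
  cat(sprintf("<signal_factors> F_A280 = %.3f +/- %.3f (reference %g/%g uM)\n",
              x$f_a280, x$f_a280_sd, x$reference_t0, x$reference_p0))
  invisible(x)
}

extinction_pair <- function(extinctions) {
  if (is.data.frame(extinctions)) {
    ext <- setNames(extinctions$extinction, extinctions$name)
    extinctions <- c(t = unname(ext[["T"]]), p = unname(ext[["P"]]))
  }
  if (is.null(names(extinctions))) names(extinctions) <- c("t", "p")
  stopifnot(all(extinctions > 0))
  extinctions
}

#' Predict normalized SEC signals from an equilibrium state
#'
#' Converts the model's high/low-MW monomer splits into the normalized A280
#' peak signals the SEC analysis reports. The high-MW signal is the
#' extinction-weighted high-MW monomer content relative to the expected signal
#' of a complete nanomaterial at the reference concentrations (50 uM of each
#' component by default); the low-MW signal is the analogous ratio for free
#' components plus early intermediates, additionally multiplied by the
#' scattering adjustment factor.
#'
#' @param state An equilibrium tibble ([solve_equilibrium()], [forward_grid()]).
#' @param extinctions Named vector `c(t = , p = )` of per-monomer molar
#'   extinction coefficients at 280 nm, or a [default_components()] tibble.
#' @param factors A [signal_factors()] object; `signal_factors(1, 0)` gives
#'   unadjusted concentration ratios.
#' @return `state` with `high_signal` and `low_signal` columns added.
#' @examples
#' st <- solve_equilibrium(tibble::tibble(t0_uM = 50, p0_uM = 50), 3.6,
#'                         species_table("simplified"))
#' predict_normalized_signals(st, factors = signal_factors(1, 0))
#' @export
predict_normalized_signals <- function(state,
                                       extinctions = default_components(),
                                       factors = signal_factors()) {
  ext <- extinction_pair(extinctions)
  denom <- factors$reference_t0 * ext[["t"]] + factors$reference_p0 * ext[["p"]]
  if (denom <= 0) abort("Reference signal denominator must be positive.")
  dplyr::mutate(
    state,
    high_signal = (.data$t_high_uM * ext[["t"]] + .data$p_high_uM * ext[["p"]]) / denom,
    low_signal = factors$f_a280 *
      (.data$t_low_uM * ext[["t"]] + .data$p_low_uM * ext[["p"]]) / denom
  )
}

#' Estimate the A280 adjustment factor from reference injections
#'
#' Ratio of the mean summed signal of the two components injected separately
#' to the mean summed signal (all peaks) of a post-assembly injection at the
#' same concentrations. Values below 1 quantify the scattering excess of the
#' assembled state. The standard deviation is propagated from the replicate
#' scatter of both datasets via [propagate_sd()].
#'
#' @param component_totals Numeric vector: per-replicate summed A280 signal of
#'   the two separate component injections.
#' @param assembled_totals Numeric vector: per-replicate summed signal (high +
#'   low MW peaks) of assembled-material injections.
#' @param reference_t0,reference_p0 Concentrations (uM) of the reference
#'   injections, recorded in the result.
#' @return A [signal_factors()] object.
#' @examples
#' adjustment_factor(89, 100)  # 0.89, the I53-40-like case
#' @export
adjustment_factor <- function(component_totals, assembled_totals,
                              reference_t0 = 50, reference_p0 = 50) {
  stopifnot(length(component_totals) >= 1L, length(assembled_totals) >= 1L)
  cm <- mean(component_totals)
  am <- mean(assembled_totals)
  if (am == 0) abort("Assembled-run summed signal is zero.")
  f <- cm / am
  csd <- if (length(component_totals) > 1L) stats::sd(component_totals) else 0
  asd <- if (length(assembled_totals) > 1L) stats::sd(assembled_totals) else 0
  fsd <- propagate_sd(cm, csd, am, asd)
  signal_factors(f_a280 = f, f_a280_sd = fsd,
                 reference_t0 = reference_t0, reference_p0 = reference_p0)
}

#' Normalize raw SEC peak areas against reference injections
#'
#' Applies the two-reference normalization used throughout the analysis:
#' nanomaterial (high-MW) peak areas are divided by the average total signal
#' of the equimolar reference assemblies (six 50 uM assemblies in the
#' reference experiments), and unassembled (low-MW) peak areas by the sum of
#' the mean areas of the two separate component injections. Reference rows are
#' identified by `is_reference`/`injection_type`; missing references are an
#' error, never a silent default, and normalizing an already-normalized
#' dataset is an error.
#'
#' @param records A peak-area tibble with columns `system`, `series_id`,
#'   `t0_uM`, `p0_uM`, `replicate`, `high_mw_area`, `low_mw_area`,
#'   `is_reference`, `injection_type` (see [read_peak_areas()]).
#' @return The assembly rows of `records` with `high_norm` and `low_norm`
#'   columns added. Attributes `normalized`, `ref_high` (mean, sd, n of the
#'   reference assembly totals) and `ref_low` (the component-injection
#'   denominator and its sd) record the normalization.
#' @export
normalize_peak_areas <- function(records) {
  if (isTRUE(attr(records, "normalized"))) {
    abort("Dataset is already normalized; normalization is not idempotent.")
  }
  needed <- c("t0_uM", "p0_uM", "high_mw_area", "low_mw_area",
              "is_reference", "injection_type")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  refs <- records[records$is_reference & records$injection_type == "assembly", ]
  comp_t <- records[records$injection_type == "component_t", ]
  comp_p <- records[records$injection_type == "component_p", ]
  if (nrow(refs) == 0L) {
    abort("No equimolar reference assemblies (is_reference & injection_type == 'assembly').")
  }
  if (nrow(comp_t) == 0L || nrow(comp_p) == 0L) {
    abort("Separate component injections (component_t / component_p) are required.")
  }
  ref_totals <- refs$high_mw_area + refs$low_mw_area
  den_high <- mean(ref_totals)
  comp_t_area <- comp_t$high_mw_area + comp_t$low_mw_area
  comp_p_area <- comp_p$high_mw_area + comp_p$low_mw_area
  den_low <- mean(comp_t_area) + mean(comp_p_area)
  if (den_high <= 0 || den_low <= 0) abort("Reference denominators must be positive.")

  out <- records[records$injection_type == "assembly", ]
  out <- dplyr::mutate(out,
                       high_norm = .data$high_mw_area / den_high,
                       low_norm = .data$low_mw_area / den_low)
  attr(out, "normalized") <- TRUE
  attr(out, "ref_high") <- c(
    mean = den_high,
    sd = if (length(ref_totals) > 1L) stats::sd(ref_totals) else 0,
    n = nrow(refs))
  var_or_0 <- function(v) if (length(v) > 1L) stats::var(v) else 0
  attr(out, "ref_low") <- c(
    mean = den_low,
    sd = sqrt(var_or_0(comp_t_area) + var_or_0(comp_p_area)))
  out
}

#' Standard deviation of a ratio of noisy means
#'
#' First-order error propagation for `f = X / E`:
#' `|f| * sqrt((sd_X/X)^2 + (sd_E/E)^2)`. Used wherever a replicate-averaged
#' signal is divided by a replicate-averaged reference (normalization,
#' adjustment factors, chevron error bars).
#'
#' @param x_mean,x_sd Mean and standard deviation of the numerator dataset.
#' @param e_mean,e_sd Mean and standard deviation of the denominator dataset.
#' @return Standard deviation of the ratio (vectorized).
#' @examples
#' propagate_sd(100, 10, 100, 10)  # 0.1414...
#' @export
propagate_sd <- function(x_mean, x_sd, e_mean, e_sd) {
  if (any(x_mean == 0) || any(e_mean == 0)) {
    abort("Ratio error propagation requires non-zero means.")
  }
  abs(x_mean / e_mean) * sqrt((x_sd / x_mean)^2 + (e_sd / e_mean)^2)
}
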