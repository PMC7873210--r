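#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # unit mean
}

# Shared machinery: solve the model at each (t0, p0), emit raw peak-area
# records plus reference and component injections. Raw areas are
# extinction-weighted monomer signals scaled by `area_scale`; the assembled
# (high-MW) peak carries the 1/f scattering excess and the residual
# (low-MW) peak the f-fold convention of the signal model, so that the
# normalize -> predict chain is exactly self-consistent at zero noise.
# Reference injections are idealized as fully assembled complete nanomaterial.
sim_peak_records <- function(points, dg_con, species, extinctions, factors,
                             noise_cv, replicates, n_reference, n_component,
                             system, area_scale, temperature) {
  ext <- extinction_pair(extinctions)
  f <- factors$f_a280
  st <- solve_equilibrium(points[, c("t0_uM", "p0_uM")],
                          thermo_params(dg_con, temperature), species)
  sig_high <- st$t_high_uM * ext[["t"]] + st$p_high_uM * ext[["p"]]
  sig_low <- st$t_low_uM * ext[["t"]] + st$p_low_uM * ext[["p"]]
  ref_sig <- factors$reference_t0 * ext[["t"]] + factors$reference_p0 * ext[["p"]]

  one_rep <- function(rep_i) {
    k <- nrow(points)
    tibble::tibble(
      system = system,
      series_id = points$series_id,
      t0_uM = points$t0_uM, p0_uM = points$p0_uM,
      replicate = rep_i,
      high_mw_area = area_scale * (sig_high / f) * lognormal_noise(k, noise_cv),
      low_mw_area = area_scale * (f * sig_low) * lognormal_noise(k, noise_cv),
      is_reference = FALSE,
      injection_type = "assembly")
  }
  assemblies <- purrr::map_dfr(seq_len(replicates), one_rep)

  refs <- tibble::tibble(
    system = system, series_id = "reference",
    t0_uM = factors$reference_t0, p0_uM = factors$reference_p0,
    replicate = seq_len(n_reference),
    high_mw_area = area_scale * (ref_sig / f) *
      lognormal_noise(n_reference, noise_cv),
    low_mw_area = 0,
    is_reference = TRUE, injection_type = "assembly")
  comps <- dplyr::bind_rows(
    tibble::tibble(
      system = system, series_id = "component",
      t0_uM = factors$reference_t0, p0_uM = 0,
      replicate = seq_len(n_component),
      high_mw_area = 0,
      low_mw_area = area_scale * factors$reference_t0 * ext[["t"]] *
        lognormal_noise(n_component, noise_cv),
      is_reference = TRUE, injection_type = "component_t"),
    tibble::tibble(
      system = system, series_id = "component",
      t0_uM = 0, p0_uM = factors$reference_p0,
      replicate = seq_len(n_component),
      high_mw_area = 0,
      low_mw_area = area_scale * factors$reference_p0 * ext[["p"]] *
        lognormal_noise(n_component, noise_cv),
      is_reference = TRUE, injection_type = "component_p"))
  out <- dplyr::bind_rows(assemblies, refs, comps)
  attr(out, "generating") <- list(dg_con = dg_con, noise_cv = noise_cv,
                                  f_a280 = f, area_scale = area_scale,
                                  temperature = temperature)
  out
}

#' Simulate a cooperativity (variable-stoichiometry) SEC dataset
#'
#' Emulates the variable-stoichiometry assembly experiment: one component held
#' constant (50 uM in the reference design) while the other is varied from
#' 0.25:1 to 3:1, in two series (variable trimer, variable pentamer), with
#' triplicate injections, six equimolar reference assemblies and separate
#' component injections. At each concentration pair the equilibrium model is
#' solved at the generating contact energy, extinction-weighted peak areas are
#' derived (the assembled peak carries the 1/f scattering excess), and
#' replicate-level multiplicative lognormal noise is applied. Identical seeds
#' reproduce identical datasets.
#'
#' @param dg_con Generating contact-energy magnitude, kcal/mol.
#' @param constant_conc Constant-component concentration, uM.
#' @param variable_values Variable-component concentrations, uM.
#' @param vary Which series to generate: subset of `c("t", "p")`.
#' @param species,extinctions,factors Model configuration (see
#'   [predict_normalized_signals()]).
#' @param noise_cv Fractional replicate standard deviation of the
#'   multiplicative noise (0.05 emulates the few-percent replicate scatter of
#'   the reference experiments).
#' @param replicates Technical replicates per assembly point.
#' @param n_reference,n_component Number of reference-assembly and per-
#'   component injections.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG state.
#' @param system Label recorded in the `system` column.
#' @param area_scale Arbitrary area units per extinction-weighted uM.
#' @param temperature Absolute temperature, K.
#' @return A raw peak-area tibble in the [read_peak_areas()] schema, ready for
#'   [normalize_peak_areas()]. The generating parameters are stored in the
#'   `generating` attribute.
#' @examples
#' dat <- sim_cooperativity_dataset(3.6, seed = 42, noise_cv = 0)
#' dplyr::count(dat, series_id)
#' @export
sim_cooperativity_dataset <- function(dg_con, constant_conc = 50,
                                      variable_values = c(12.5, 25, 37.5, 50,
                                                          75, 100, 125, 150),
                                      vary = c("t", "p"),
                                      species = species_table("inclusive"),
                                      extinctions = default_components(),
                                      factors = signal_factors(),
                                      noise_cv = 0.05, replicates = 3,
                                      n_reference = 6, n_component = 3,
                                      seed = NULL, system = "synthetic",
                                      area_scale = 1, temperature = 296) {
  vary <- match.arg(vary, several.ok = TRUE)
  stopifnot(all(variable_values > 0), constant_conc > 0)
  points <- dplyr::bind_rows(
    if ("t" %in% vary) tibble::tibble(series_id = "vary_t",
                                      t0_uM = variable_values,
                                      p0_uM = constant_conc),
    if ("p" %in% vary) tibble::tibble(series_id = "vary_p",
                                      t0_uM = constant_conc,
                                      p0_uM = variable_values))
  gen <- function() sim_peak_records(points, dg_con, species, extinctions,
                                     factors, noise_cv, replicates,
                                     n_reference, n_component, system,
                                     area_scale, temperature)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate an equimolar assembly series
#'
#' As [sim_cooperativity_dataset()], but with \[T\]0 = \[P\]0 swept over a
#' range of total input concentrations spanning the pseudo-critical region.
#'
#' @inheritParams sim_cooperativity_dataset
#' @param totals Per-component input concentrations, uM (each point has
#'   t0 = p0 = the value).
#' @return A raw peak-area tibble (series `"equimolar"`).
#' @export
sim_equimolar_series <- function(dg_con,
                                 totals = c(5, 10, 15, 20, 25, 37.5, 50, 75, 100),
                                 species = species_table("inclusive"),
                                 extinctions = default_components(),
                                 factors = signal_factors(),
                                 noise_cv = 0.05, replicates = 3,
                                 n_reference = 6, n_component = 3,
                                 seed = NULL, system = "synthetic",
                                 area_scale = 1, temperature = 296) {
  stopifnot(all(totals > 0))
  points <- tibble::tibble(series_id = "equimolar", t0_uM = totals,
                           p0_uM = totals)
  gen <- function() sim_peak_records(points, dg_con, species, extinctions,
                                     factors, noise_cv, replicates,
                                     n_reference, n_component, system,
                                     area_scale, temperature)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate an SEC chromatogram from a solved equilibrium state
#'
#' Renders a solved state as an idealized absorbance trace on a 24 mL
#' analytical column: Gaussian peaks centered at the assembled-material and
#' free-component elution volumes with areas proportional to the predicted
#' high- and low-MW signals. A companion integrator, [integrate_chromatogram()],
#' recovers the areas for round-trip testing of peak quantification.
#'
#' @param state A one-row equilibrium tibble with signal columns (run through
#'   [predict_normalized_signals()]), or with monomer splits from which the
#'   unadjusted signals are computed using `extinctions`.
#' @param extinctions Extinction coefficients (used when signal columns are
#'   absent).
#' @param centers Elution centers, mL: `c(assembled = 12, components = 16)`.
#' @param widths Gaussian SD of each peak, mL.
#' @param volume_step,total_volume Trace sampling, mL.
#' @param min_separation Minimum allowed center separation in units of the
#'   summed widths; closer peaks are an error (no baseline separation).
#' @return A tibble with columns `volume_mL`, `a280`, and attribute `areas`
#'   (the generating peak areas).
#' @export
sim_chromatogram <- function(state, extinctions = default_components(),
                             centers = c(assembled = 12, components = 16),
                             widths = c(assembled = 0.35, components = 0.35),
                             volume_step = 0.02, total_volume = 24,
                             min_separation = 4) {
  stopifnot(nrow(state) == 1L)
  if (!all(c("high_signal", "low_signal") %in% names(state))) {
    state <- predict_normalized_signals(state, extinctions,
                                        signal_factors(1, 0))
  }
  sep <- abs(centers[["components"]] - centers[["assembled"]])
  if (sep < min_separation * sum(widths)) {
    abort("Peaks are not baseline-separated at the requested centers/widths.")
  }
  vol <- seq(0, total_volume, by = volume_step)
  areas <- c(assembled = state$high_signal[1], components = state$low_signal[1])
  a280 <- areas[["assembled"]] *
    stats::dnorm(vol, centers[["assembled"]], widths[["assembled"]]) +
    areas[["components"]] *
    stats::dnorm(vol, centers[["components"]], widths[["components"]])
  out <- tibble::tibble(volume_mL = vol, a280 = a280)
  attr(out, "areas") <- areas
  attr(out, "centers") <- centers
  out
}

#' Integrate an SEC chromatogram by the trapezoidal rule
#'
#' Splits the trace at the midpoint between the two peak centers and
#' integrates each side with the trapezoidal rule. With baseline-separated
#' peaks the recovered areas round-trip the generating areas to well within
#' 1%.
#'
#' @param trace A chromatogram tibble (`volume_mL`, `a280`).
#' @param split_at Volume (mL) separating the assembled and component peaks;
#'   defaults to the midpoint of the `centers` attribute, or 14 mL.
#' @return A tibble with `peak` (`"assembled"`, `"components"`) and `area`.
#' @export
integrate_chromatogram <- function(trace, split_at = NULL) {
  centers <- attr(trace, "centers")
  split_at <- split_at %||%
    (if (!is.null(centers)) mean(centers) else 14)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  left <- trace$volume_mL <= split_at
  tibble::tibble(
    peak = c("assembled", "components"),
    area = c(trapz(trace$volume_mL[left], trace$a280[left]),
             trapz(trace$volume_mL[!left], trace$a280[!left])))
}

#' Simulate a thermal melt curve
#'
#' Logistic transition plus linear baseline drift plus seeded Gaussian noise,
#' at assay-typical amplitudes (negative MRE loss for CD, negative nm shift
#' for BCM, positive counts for SLS). Fixture generator for the thermal
#' callers.
#'
#' @param tm Transition midpoint, degrees C (within the scan range).
#' @param amplitude Total signal change across the transition (signed).
#' @param baseline0 Signal at the starting temperature.
#' @param baseline_drift Linear drift, signal units per degree C.
#' @param transition_width Logistic scale parameter, degrees C.
#' @param temperatures Scan grid, degrees C.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param assay Assay label attached to the curve.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [melt_curve()] tibble.
#' @examples
#' tm_by_derivative(sim_melt_curve(70, noise_sd = 0, seed = 1))
#' @export
sim_melt_curve <- function(tm, amplitude = NULL, baseline0 = NULL,
                           baseline_drift = 0, transition_width = 2,
                           temperatures = seq(25, 95, by = 1),
                           noise_sd = 0,
                           assay = c("cd_mre", "nanodsf_bcm", "sls_counts",
                                     "activity"),
                           seed = NULL) {
  assay <- match.arg(assay)
  if (tm < min(temperatures) || tm > max(temperatures)) {
    abort("`tm` must lie within the temperature scan range.")
  }
  amplitude <- amplitude %||% switch(assay, cd_mre = 8000, nanodsf_bcm = -4.5,
                                     sls_counts = 60000, activity = -1)
  baseline0 <- baseline0 %||% switch(assay, cd_mre = -9000, nanodsf_bcm = 337,
                                     sls_counts = 0, activity = 1)
  gen <- function() {
    sig <- baseline0 + baseline_drift * (temperatures - temperatures[1]) +
      amplitude / (1 + exp(-(temperatures - tm) / transition_width)) +
      rnorm(length(temperatures), sd = noise_sd)
    melt_curve(temperatures, sig, assay = assay)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
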