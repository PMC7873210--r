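peak_area_cols <- c("system", "series_id", "t0_uM", "p0_uM", "replicate",
                    "high_mw_area", "low_mw_area", "is_reference",
                    "injection_type")

#' Read a SEC peak-area dataset
#'
#' CSV schema: columns `system`, `series_id`, `t0_uM`, `p0_uM`, `replicate`,
#' `high_mw_area`, `low_mw_area`, `is_reference` (logical), `injection_type`
#' (`assembly`, `component_t`, `component_p`). Lines beginning with `#` are
#' metadata comments. Validation failures report the offending rows.
#'
#' @param path File path.
#' @return A raw peak-area tibble.
#' @export
read_peak_areas <- function(path) {
  dat <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      system = readr::col_character(),
      series_id = readr::col_character(),
      t0_uM = readr::col_double(),
      p0_uM = readr::col_double(),
      replicate = readr::col_integer(),
      high_mw_area = readr::col_double(),
      low_mw_area = readr::col_double(),
      is_reference = readr::col_logical(),
      injection_type = readr::col_character()))
  missing_cols <- setdiff(peak_area_cols, names(dat))
  if (length(missing_cols)) {
    abort(paste0("Peak-area file lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_area <- which(dat$high_mw_area < 0 | dat$low_mw_area < 0)
  if (length(bad_area)) {
    abort(paste0("Negative peak areas at data row(s): ",
                 paste(bad_area, collapse = ", ")))
  }
  bad_type <- which(!dat$injection_type %in%
                      c("assembly", "component_t", "component_p"))
  if (length(bad_type)) {
    abort(paste0("Unknown injection_type at data row(s): ",
                 paste(bad_type, collapse = ", ")))
  }
  bad_conc <- which(dat$t0_uM < 0 | dat$p0_uM < 0 |
                      !is.finite(dat$t0_uM) | !is.finite(dat$p0_uM))
  if (length(bad_conc)) {
    abort(paste0("Invalid concentrations at data row(s): ",
                 paste(bad_conc, collapse = ", ")))
  }
  dat
}

#' Write a SEC peak-area dataset
#'
#' Writes the documented CSV schema; metadata (e.g. the `generating`
#' attribute of simulated datasets) is embedded as `# key: value` comment
#' lines so provenance survives the round trip.
#'
#' @param records A peak-area tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_peak_areas <- function(records, path) {
  gen <- attr(records, "generating")
  lines <- character(0)
  if (!is.null(gen)) {
    lines <- sprintf("# %s: %.12g", names(gen), unlist(gen))
  }
  writeLines(lines, path)
  readr::write_csv(dplyr::select(records, dplyr::all_of(peak_area_cols)),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a melt curve
#'
#' CSV with `# assay:`, `# sample:`, `# ratio:` header comments and columns
#' `temperature_C`, `signal`.
#'
#' @param path File path.
#' @return A [melt_curve()] tibble.
#' @export
read_melt_curve <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  assay <- get_meta("assay")
  melt_curve(dat$temperature_C, dat$signal,
             assay = if (is.na(assay)) "cd_mre" else assay,
             sample = get_meta("sample"), ratio = get_meta("ratio"))
}

#' Write a melt curve
#'
#' @param curve A [melt_curve()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_melt_curve <- function(curve, path) {
  writeLines(c(paste0("# assay: ", attr(curve, "assay") %||% "cd_mre"),
               paste0("# sample: ", attr(curve, "sample") %||% NA),
               paste0("# ratio: ", attr(curve, "ratio") %||% NA)),
             path)
  readr::write_csv(curve, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Analysis presets for the reference systems
#'
#' Bundles the per-system constants of the reference analyses: the A280
#' adjustment factor (0.89 +/- 0.06 for I53-40, 0.90 +/- 0.04 for I53-50),
#' the equimolar-plane bin width (0.5 uM for I53-40, 0.0625 uM for the more
#' steeply assembling I53-50), and the fitting restriction (I53-50 assembles
#' aberrantly when pentamer is super-stoichiometric, so only points with
#' \[T\]0 >= \[P\]0 enter its fit). Extinction coefficients default to the
#' package's synthetic placeholders and should be overridden with measured
#' values.
#'
#' @param system `"I53-40"`, `"I53-50"` or `"custom"`.
#' @param extinctions Component tibble or named extinction pair.
#' @return A list of class `system_preset` with elements `system`, `factors`,
#'   `bin_width`, `restriction`, `extinctions`.
#' @export
system_preset <- function(system = c("I53-40", "I53-50", "custom"),
                          extinctions = default_components()) {
  system <- match.arg(system)
  cfg <- switch(system,
    "I53-40" = list(factors = signal_factors(0.89, 0.06), bin_width = 0.5,
                    restriction = NULL),
    "I53-50" = list(factors = signal_factors(0.90, 0.04), bin_width = 0.0625,
                    restriction = "t0_ge_p0"),
    custom = list(factors = signal_factors(1, 0), bin_width = 0.5,
                  restriction = NULL))
  structure(c(list(system = system), cfg, list(extinctions = extinctions)),
            class = "system_preset")
}

#' Run the full assembly analysis pipeline
#'
#' Normalizes a raw peak-area dataset, fits the contact energy, and computes
#' the cooperativity statistics (Hill analysis on the equimolar series if one
#' is present, chevron summary on the variable-stoichiometry series). When
#' `out_dir` is given, all tables are persisted as CSV and a JSON summary
#' records the parameters and results.
#'
#' @param records A raw peak-area tibble ([read_peak_areas()] or a
#'   simulator), or an already-normalized one.
#' @param system A system name or [system_preset()].
#' @param species [species_table()] used by the fit.
#' @param dg_scan Contact-energy scan grid, kcal/mol.
#' @param out_dir Optional output directory.
#' @return A list of class `assembly_pipeline` with elements `fit`
#'   ([fit_dgcon()]), `hill` (or NULL), `chevron` (or NULL), `normalized`,
#'   and `summary`.
#' @export
run_assembly_pipeline <- function(records, system = "I53-40",
                                  species = species_table("inclusive"),
                                  dg_scan = seq(2.5, 5.5, by = 0.01),
                                  out_dir = NULL) {
  preset <- if (inherits(system, "system_preset")) system else system_preset(system)
  if (nrow(records) == 0L) abort("Empty dataset; nothing to analyze.")
  normalized <- if (isTRUE(attr(records, "normalized"))) records else
    normalize_peak_areas(records)
  fit <- fit_dgcon(normalized, species = species,
                   extinctions = preset$extinctions,
                   factors = preset$factors, dg_scan = dg_scan,
                   restriction = preset$restriction)
  eq <- normalized[normalized$t0_uM == normalized$p0_uM &
                     !normalized$is_reference, ]
  hill <- if (nrow(eq) >= 2L) {
    tryCatch(hill_analysis(eq, preset$factors), error = function(e) NULL)
  }
  coop <- normalized[normalized$series_id %in% c("vary_t", "vary_p"), ]
  chev <- if (nrow(coop)) {
    chevron_summary(coop, preset$extinctions, preset$factors)
  }
  summary <- list(
    system = preset$system,
    restriction = fit$restriction,
    dg_best = fit$dg_best,
    rmspe_min = fit$rmspe_min,
    hill_coefficient = if (!is.null(hill)) hill$hill_coefficient,
    apparent_kd_uM = if (!is.null(hill)) hill$apparent_kd_uM,
    n_points = fit$n_points,
    dg_scan = fit$dg_scan,
    f_a280 = preset$factors$f_a280)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fit$profile, file.path(out_dir, "rmspe_profile.csv"))
    readr::write_csv(fit$predictions, file.path(out_dir, "fit_predictions.csv"))
    if (!is.null(chev)) readr::write_csv(chev, file.path(out_dir, "chevron.csv"))
    if (!is.null(hill)) readr::write_csv(hill$points, file.path(out_dir, "hill_points.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(fit = fit, hill = hill, chevron = chev,
                 normalized = normalized, summary = summary),
            class = "assembly_pipeline")
}

#' @export
print.assembly_pipeline <- function(x, ...) {
  cat("<assembly_pipeline>\n")
  print(x$fit)
  if (!is.null(x$hill)) print(x$hill)
  if (!is.null(x$chevron)) {
    cat(sprintf("  chevron: %d series points\n", nrow(x$chevron)))
  }
  invisible(x)
}
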