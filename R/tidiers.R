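#' Tidy a contact-energy fit
#'
#' @param x A `dgcon_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate` (kcal/mol) and the RMSPE at
#'   the minimum.
#' @export
tidy.dgcon_fit <- function(x, ...) {
  tibble::tibble(term = "dg_con", estimate = x$dg_best,
                 rmspe = x$rmspe_min)
}

#' @rdname tidy.dgcon_fit
#' @export
glance.dgcon_fit <- function(x, ...) {
  tibble::tibble(dg_best = x$dg_best, rmspe_min = x$rmspe_min,
                 n_points = x$n_points, use = x$use,
                 restriction = x$restriction,
                 dg_scan_min = x$dg_scan[1], dg_scan_max = x$dg_scan[2],
                 boundary = x$boundary)
}

#' Tidy a Hill analysis
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with the Hill coefficient and apparent KD.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("hill_coefficient", "apparent_kd_uM"),
                 estimate = c(x$hill_coefficient, x$apparent_kd_uM))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(hill_coefficient = x$hill_coefficient,
                 apparent_kd_uM = x$apparent_kd_uM,
                 r_squared = x$r_squared, n_points = x$n_points,
                 theta_min = x$theta_range[1], theta_max = x$theta_range[2])
}
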