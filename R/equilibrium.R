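#' Thermodynamic parameters of the assembly model
#'
#' @param dg_con Magnitude of the average per-contact association free energy,
#'   kcal/mol, stored as a positive number. The contact is favorable: a larger
#'   magnitude drives more assembly. Internally the Boltzmann factor of a
#'   species with `c` contacts is `exp(c * dg_con / (R * T))`; the sign
#'   convention is fixed so that the stored magnitude is the number quoted for
#'   these systems (3-4 kcal/mol per contact).
#' @param temperature Absolute temperature in K. All reference experiments were
#'   performed at ambient temperature, 296 K.
#' @param gas_constant Gas constant in kcal/(mol K).
#' @return A list of class `thermo_params`.
#' @examples
#' thermo_params(3.6)
#' @export
thermo_params <- function(dg_con, temperature = 296,
                          gas_constant = 1.98720e-3) {
  stopifnot(is.numeric(dg_con), length(dg_con) == 1L, dg_con >= 0,
            temperature > 0, gas_constant > 0)
  structure(list(dg_con = dg_con, temperature = temperature,
                 gas_constant = gas_constant),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> |dG_con| = %.3f kcal/mol at %g K\n",
              x$dg_con, x$temperature))
  invisible(x)
}

as_thermo_params <- function(params) {
  if (inherits(params, "thermo_params")) return(params)
  if (is.numeric(params) && length(params) == 1L) return(thermo_params(params))
  abort("`params` must be a `thermo_params` object or a single dG_con value.")
}

LN1E6 <- log(1e6)  # uM -> M conversion in log space

#' Log-domain species concentration
#'
#' Natural log of the molar equilibrium concentration of an assembly species
#' given free (unassembled) monomer concentrations. For a species with `a`
#' trimeric and `b` pentameric building blocks, `c` contacts and symmetry `s`,
#'
#'   ln conc = a ln(\[T\]/1e6) + b ln(\[P\]/1e6) + c dG_con/(R T) - ln s
#'
#' with \[T\], \[P\] the free monomer concentrations in uM (the prefactor
#' 3^a 5^b and the building-block divisors 3e6, 5e6 of the mass-action law
#' cancel to the monomer-molar form above). All arithmetic stays in the log
#' domain: at dG_con of several kcal/mol the Boltzmann factor of the complete
#' assembly is ~e^370 while the concentration product is ~e^-390, and neither
#' factor is representable in double precision on its own.
#'
#' @param species A species table row set ([species_table()]); recycled against
#'   the free concentrations if either has length one.
#' @param free_t,free_p Free trimeric / pentameric monomer concentrations, uM.
#'   Zero maps to `-Inf` (species absent).
#' @param params [thermo_params()] or a bare dG_con magnitude.
#' @return Numeric vector of ln(concentration in M), one per species row and
#'   free-state pair.
#' @examples
#' sp <- species_table("inclusive")
#' log_species_concentration(sp[sp$species_id == "T3P5", ], 3, 5, 0)
#' # ln(1.5e-11): 3 uM * 5 uM with unit Boltzmann factor
#' @export
log_species_concentration <- function(species, free_t, free_p, params) {
  params <- as_thermo_params(params)
  if (any(free_t < 0) || any(free_p < 0)) {
    abort("Free concentrations must be >= 0.")
  }
  energy <- params$dg_con / (params$gas_constant * params$temperature)
  species$n_trimers * (log(free_t) - LN1E6) +
    species$n_pentamers * (log(free_p) - LN1E6) +
    species$contacts * energy - log(species$symmetry)
}

# log(sum(exp(cols))) row-wise over a matrix, overflow-safe
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  finite <- is.finite(mx)
  out <- mx
  if (any(finite)) {
    out[finite] <- mx[finite] +
      log(rowSums(exp(m[finite, , drop = FALSE] - mx[finite])))
  }
  out
}

# Nested-bisection solve of the log mass-balance system, vectorized over
# points. Inner loop: for fixed ln free_p, bisect ln free_t so the predicted
# ln t0 matches its target (strictly increasing). Outer loop: bisect
# ln free_p on the t0-feasible manifold. Slow but unconditionally convergent.
solve_by_bisection <- function(lt0, lp0, params, species, n_bisect = 90L) {
  f_t <- function(xv, yv) {
    eval_free_states(exp(xv), exp(yv), params, species)$ln_t0 - lt0
  }
  inner_x <- function(yv) {
    hi <- lt0
    lo <- lt0 - 10
    repeat {
      f <- f_t(lo, yv)
      if (all(f < 0)) break
      lo[f >= 0] <- lo[f >= 0] - 20
    }
    for (i in seq_len(n_bisect)) {
      mid <- (lo + hi) / 2
      pos <- f_t(mid, yv) > 0
      hi <- ifelse(pos, mid, hi)
      lo <- ifelse(pos, lo, mid)
    }
    (lo + hi) / 2
  }
  g_p <- function(yv) {
    eval_free_states(exp(inner_x(yv)), exp(yv), params,
                     species)$ln_p0 - lp0
  }
  hi <- lp0
  lo <- lp0 - 10
  repeat {
    g <- g_p(lo)
    if (all(g < 0)) break
    lo[g >= 0] <- lo[g >= 0] - 20
  }
  for (i in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    pos <- g_p(mid) > 0
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
  }
  y <- (lo + hi) / 2
  list(x = inner_x(y), y = y)
}

# Evaluate all per-species logs and derived totals for vectors of free
# concentrations (uM). Returns a list of matrices/vectors used by both the
# forward and inverse parameterizations.
eval_free_states <- function(free_t, free_p, params, species) {
  params <- as_thermo_params(params)
  n <- length(free_t)
  energy <- params$dg_con / (params$gas_constant * params$temperature)
  x <- log(free_t)  # may be -Inf
  y <- log(free_p)
  # n x k matrix of ln species concentration (M)
  lc <- outer(x - LN1E6, species$n_trimers) +
    outer(y - LN1E6, species$n_pentamers) +
    matrix(species$contacts * energy - log(species$symmetry),
           n, nrow(species), byrow = TRUE)
  lc[!is.finite(lc)] <- -Inf
  # monomer-equivalent uM contributed by each species
  lt <- sweep(lc, 2L, log(species$t_monomers), "+") + LN1E6
  lp <- sweep(lc, 2L, log(species$p_monomers), "+") + LN1E6
  list(x = x, y = y, lc = lc, lt = lt, lp = lp,
       ln_t0 = logsumexp_rows(cbind(x, lt)),
       ln_p0 = logsumexp_rows(cbind(y, lp)))
}

assemble_state_tbl <- function(ev, species, t0 = NULL, p0 = NULL,
                               converged = TRUE) {
  conc <- exp(ev$lc)
  colnames(conc) <- paste0("conc_", species$species_id)
  high <- species$mw_class == "high"
  t_high <- rowSums(exp(ev$lt[, high, drop = FALSE]))
  p_high <- rowSums(exp(ev$lp[, high, drop = FALSE]))
  t_low <- exp(ev$x) + rowSums(exp(ev$lt[, !high, drop = FALSE]))
  p_low <- exp(ev$y) + rowSums(exp(ev$lp[, !high, drop = FALSE]))
  t0 <- t0 %||% exp(ev$ln_t0)
  p0 <- p0 %||% exp(ev$ln_p0)
  out <- tibble::tibble(
    t0_uM = t0, p0_uM = p0,
    free_t_uM = exp(ev$x), free_p_uM = exp(ev$y)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(conc))
  out$t_high_uM <- t_high
  out$p_high_uM <- p_high
  out$t_low_uM <- t_low
  out$p_low_uM <- p_low
  out$high_mw_uM <- t_high + p_high
  out$low_mw_uM <- t_low + p_low
  tot <- t0 + p0
  out$mass_fraction <- ifelse(tot > 0, pmin(out$high_mw_uM / tot, 1), 0)
  out$converged <- converged
  class(out) <- c("equilibrium_tbl", class(out))
  out
}

#' Totals implied by free component concentrations
#'
#' Mass-balance bookkeeping of the forward parameterization: given free
#' monomer concentrations, sums the monomer equivalents locked in every
#' modeled species to give the input totals \[T\]0 and \[P\]0 that would
#' produce this free state at equilibrium. For the simplified table this is
#' \[T\]0 = 60 \[T60P60\] 1e6 + \[T\] (and analogously for P).
#'
#' @param free A data frame with columns `free_t_uM` and `free_p_uM`.
#' @param params [thermo_params()] or a dG_con magnitude.
#' @param species A [species_table()].
#' @return `free` as a tibble with `t0_uM` and `p0_uM` columns added.
#' @export
totals_from_free <- function(free, params, species = species_table()) {
  stopifnot(all(c("free_t_uM", "free_p_uM") %in% names(free)))
  if (any(free$free_t_uM < 0) || any(free$free_p_uM < 0)) {
    abort("Free concentrations must be >= 0.")
  }
  ev <- eval_free_states(free$free_t_uM, free$free_p_uM, params, species)
  dplyr::mutate(tibble::as_tibble(free),
                t0_uM = exp(ev$ln_t0), p0_uM = exp(ev$ln_p0))
}

#' Forward evaluation of the equilibrium model on a free-concentration grid
#'
#' Evaluates every combination of the supplied free trimer and pentamer
#' monomer concentrations, returning the full equilibrium state at each grid
#' point (species concentrations, implied totals, high/low-MW monomer splits
#' and assembled mass fraction). This is the parameterization in which the
#' model is a closed form; the 3D surfaces over (\[T\]0, \[P\]0) are produced
#' by evaluating a dense grid and slicing/binning with [slice_and_bin()].
#'
#' @param t_free,p_free Strictly positive free monomer concentrations, uM.
#' @param params [thermo_params()] or a dG_con magnitude.
#' @param species A [species_table()].
#' @return An equilibrium tibble, one row per grid point, with columns
#'   `t0_uM`, `p0_uM`, `free_t_uM`, `free_p_uM`, one `conc_*` column per
#'   species (M), monomer splits `t_high_uM`, `p_high_uM`, `t_low_uM`,
#'   `p_low_uM`, `high_mw_uM`, `low_mw_uM`, and `mass_fraction`.
#' @examples
#' forward_grid(c(1, 5), c(1, 5), thermo_params(3.6))
#' @export
forward_grid <- function(t_free, p_free, params,
                         species = species_table("inclusive")) {
  if (length(t_free) == 0L || length(p_free) == 0L) {
    abort("Free-concentration arrays must be non-empty.")
  }
  if (any(!is.finite(t_free)) || any(!is.finite(p_free)) ||
      any(t_free <= 0) || any(p_free <= 0)) {
    abort("Free-concentration arrays must be strictly positive and finite.")
  }
  grid <- tidyr::expand_grid(free_t_uM = t_free, free_p_uM = p_free)
  ev <- eval_free_states(grid$free_t_uM, grid$free_p_uM, params, species)
  assemble_state_tbl(ev, species)
}

#' Solve the equilibrium model for given input totals
#'
#' Inverse of the forward parameterization: finds the free monomer
#' concentrations at which the mass balance reproduces the supplied input
#' totals \[T\]0, \[P\]0, then returns the full equilibrium state. The totals
#' are posynomials in the free concentrations, so the system is solved by
#' damped Newton iteration on (ln free_t, ln free_p) with the analytic
#' Jacobian, entirely in the log domain; the log-space residual is monotone in
#' each variable, which makes the solution unique. Points with a zero total
#' return the all-free state (no heteromeric species can form).
#'
#' @param totals A data frame with columns `t0_uM` and `p0_uM` (or a single
#'   pair via the `t0`/`p0` shortcut arguments).
#' @param params [thermo_params()] or a dG_con magnitude.
#' @param species A [species_table()].
#' @param tol Relative mass-balance tolerance on both totals.
#' @param max_iter Newton iteration cap; non-convergence raises an error
#'   reporting the worst residual.
#' @inheritParams forward_grid
#' @return An equilibrium tibble as in [forward_grid()], rows in input order.
#' @examples
#' solve_equilibrium(tibble::tibble(t0_uM = 100, p0_uM = 100),
#'                   thermo_params(3.6), species_table("simplified"))
#' @export
solve_equilibrium <- function(totals, params,
                              species = species_table("inclusive"),
                              tol = 1e-9, max_iter = 200) {
  if (is.numeric(totals) && length(totals) == 2L) {
    totals <- tibble::tibble(t0_uM = totals[[1]], p0_uM = totals[[2]])
  }
  stopifnot(all(c("t0_uM", "p0_uM") %in% names(totals)))
  t0 <- totals$t0_uM
  p0 <- totals$p0_uM
  if (any(!is.finite(t0)) || any(!is.finite(p0)) || any(t0 < 0) || any(p0 < 0)) {
    abort("Input totals must be finite and >= 0.")
  }
  n <- length(t0)
  out_rows <- vector("list", 1L)

  degenerate <- t0 <= 0 | p0 <= 0
  x <- log(pmax(t0, .Machine$double.xmin))
  y <- log(pmax(p0, .Machine$double.xmin))
  active <- which(!degenerate)

  energy_terms <- function(xv, yv) {
    eval_free_states(exp(xv), exp(yv), params, species)
  }

  lt0 <- log(t0[active])
  lp0 <- log(p0[active])
  xa <- pmin(x[active], lt0)
  ya <- pmin(y[active], lp0)
  if (length(active)) {
    sp <- species
    # Levenberg-Marquardt on the log-space residuals
    #   F = (ln t0_pred - ln t0, ln p0_pred - ln p0).
    # Plain Newton fails here: when one assembled species dominates both
    # totals the 2x2 Jacobian is near-singular and the Newton direction is
    # cancellation noise along its near-null space. Adaptive damping
    # interpolates toward scaled gradient descent in that regime and
    # recovers quadratic convergence near the solution.
    ev <- energy_terms(xa, ya)
    f1 <- ev$ln_t0 - lt0
    f2 <- ev$ln_p0 - lp0
    norm2 <- f1^2 + f2^2
    mu <- rep(1e-8, length(xa))
    iter <- 0L
    repeat {
      res <- pmax(abs(f1), abs(f2))
      if (all(res <= tol / 2)) break
      iter <- iter + 1L
      if (iter > max_iter) break
      # Jacobian of (ln t0_pred, ln p0_pred) wrt (x, y): exponent-weighted
      # shares of each term in the totals (free monomer has exponent 1).
      j11 <- exp(logsumexp_rows(cbind(ev$x,
               sweep(ev$lt, 2L, log(sp$n_trimers), "+"))) - ev$ln_t0)
      j12 <- exp(logsumexp_rows(sweep(ev$lt, 2L, log(sp$n_pentamers), "+")) -
                 ev$ln_t0)
      j21 <- exp(logsumexp_rows(sweep(ev$lp, 2L, log(sp$n_trimers), "+")) -
                 ev$ln_p0)
      j22 <- exp(logsumexp_rows(cbind(ev$y,
               sweep(ev$lp, 2L, log(sp$n_pentamers), "+"))) - ev$ln_p0)
      # (J'J + mu diag(J'J)) d = -J'F, closed form for the 2x2 system
      a11 <- j11^2 + j21^2
      a12 <- j11 * j12 + j21 * j22
      a22 <- j12^2 + j22^2
      g1 <- j11 * f1 + j21 * f2
      g2 <- j12 * f1 + j22 * f2
      d11 <- a11 * (1 + mu)
      d22 <- a22 * (1 + mu)
      det <- d11 * d22 - a12^2
      dx <- -(d22 * g1 - a12 * g2) / det
      dy <- -(-a12 * g1 + d11 * g2) / det
      # keep proposals finite in log space
      dx <- pmin(pmax(dx, -8), 8)
      dy <- pmin(pmax(dy, -8), 8)
      ev_new <- energy_terms(xa + dx, ya + dy)
      f1n <- ev_new$ln_t0 - lt0
      f2n <- ev_new$ln_p0 - lp0
      norm_new <- f1n^2 + f2n^2
      accept <- is.finite(norm_new) & norm_new <= norm2
      mu <- ifelse(accept, pmax(mu / 3, 1e-12), pmin(mu * 8, 1e12))
      if (any(accept)) {
        xa[accept] <- xa[accept] + dx[accept]
        ya[accept] <- ya[accept] + dy[accept]
        f1[accept] <- f1n[accept]
        f2[accept] <- f2n[accept]
        norm2[accept] <- norm_new[accept]
        ev <- energy_terms(xa, ya)
      }
    }
    # In the extreme regime where assembly is essentially complete the two
    # log-total surfaces become parallel and damped iteration crawls; finish
    # any stragglers with nested bisection, which only needs monotonicity
    # (each log-total is strictly increasing in its own log-free variable,
    # and the t0-feasible manifold leaves ln p0_pred strictly increasing in
    # ln free_p because the Jacobian determinant is positive).
    bad <- pmax(abs(f1), abs(f2)) > tol / 2
    if (any(bad)) {
      bs <- solve_by_bisection(lt0[bad], lp0[bad], params, species)
      xa[bad] <- bs$x
      ya[bad] <- bs$y
      ev_chk <- energy_terms(xa[bad], ya[bad])
      res_chk <- pmax(abs(ev_chk$ln_t0 - lt0[bad]),
                      abs(ev_chk$ln_p0 - lp0[bad]))
      if (any(res_chk > tol)) {
        abort(sprintf(
          "Equilibrium solve did not converge: worst log-residual %.3e.",
          max(res_chk)))
      }
    }
    x[active] <- xa
    y[active] <- ya
  }
  x[degenerate] <- log(t0[degenerate])  # -Inf when t0 = 0
  y[degenerate] <- log(p0[degenerate])
  ev_all <- eval_free_states(exp(x), exp(y), params, species)
  assemble_state_tbl(ev_all, species, t0 = t0, p0 = p0)
}

#' Assembled mass fraction of a solved equilibrium state
#'
#' Fraction of the input material residing in the high-MW (assembled) SEC
#' class. The default basis counts monomers: high-MW monomer equivalents over
#' `t0 + p0`. The `"mass"` basis weights each monomer by its component mass,
#' which matters only when the trimer and pentamer monomers differ in MW.
#'
#' @param state An equilibrium tibble from [solve_equilibrium()] or
#'   [forward_grid()].
#' @param basis `"monomer"` (default) or `"mass"`.
#' @param components Component tibble supplying monomer masses for the
#'   `"mass"` basis.
#' @return Numeric vector in \[0, 1\], one value per state row.
#' @export
mass_fraction_assembled <- function(state, basis = c("monomer", "mass"),
                                    components = default_components()) {
  basis <- match.arg(basis)
  tot <- state$t0_uM + state$p0_uM
  if (any(tot <= 0)) abort("Mass fraction undefined for zero total input.")
  if (basis == "monomer") {
    return(pmin((state$t_high_uM + state$p_high_uM) / tot, 1))
  }
  mw <- setNames(components$monomer_mw, components$name)
  num <- state$t_high_uM * mw[["T"]] + state$p_high_uM * mw[["P"]]
  den <- state$t0_uM * mw[["T"]] + state$p0_uM * mw[["P"]]
  pmin(num / den, 1)
}
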