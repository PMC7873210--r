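#' Build the I53 icosahedral contact architecture
#'
#' Constructs the contact graph of a complete I53-class assembly: 20 trimeric
#' building blocks sit on the faces of a regular icosahedron and 12 pentameric
#' building blocks on its vertices, so the trimer-pentamer contacts are exactly
#' the face-vertex incidences. Each trimer makes 3 contacts, each pentamer 5,
#' for 60 heteromeric contacts and 20*3 + 12*5 = 120 monomeric subunits in the
#' complete assembly. Trimer-trimer and pentamer-pentamer contacts do not occur.
#'
#' The graph is realized combinatorially from the icosahedral graph (vertices =
#' pentamers, triangles = trimers); no 3D coordinates are involved.
#'
#' @param components A two-row tibble describing the building blocks, as
#'   returned by [default_components()]. Only the default 20-trimer/12-pentamer
#'   architecture is wired; the component table carries masses and extinction
#'   coefficients used downstream.
#'
#' @return An object of class `assembly_architecture`: a list with
#'   \describe{
#'     \item{components}{the component tibble,}
#'     \item{edges}{a tibble with columns `trimer` (1-20) and `pentamer`
#'       (1-12), one row per heteromeric contact,}
#'     \item{total_contacts}{integer, 60 for the default architecture.}
#'   }
#' @examples
#' arch <- i53_architecture()
#' arch$total_contacts                  # 60
#' table(arch$edges$trimer)             # every trimer has degree 3
#' @export
i53_architecture <- function(components = default_components()) {
  g <- igraph::make_graph("Icosahedral")
  tri <- igraph::cliques(g, min = 3, max = 3)
  stopifnot(length(tri) == 20L)
  edges <- purrr::imap_dfr(tri, function(face, i) {
    tibble::tibble(trimer = as.integer(i), pentamer = as.integer(face))
  })
  edges <- dplyr::arrange(edges, .data$trimer, .data$pentamer)
  structure(
    list(components = components, edges = edges,
         total_contacts = nrow(edges)),
    class = "assembly_architecture"
  )
}

#' Default building-block definitions for the I53 architecture
#'
#' One row per component class. `oligomer_size` is the number of monomers per
#' building block and `copies_complete` the number of building blocks in the
#' complete assembly. The monomer masses and molar extinction coefficients at
#' 280 nm are synthetic placeholders of realistic magnitude for small designed
#' subunits; real analyses should override them with the measured values for
#' the system at hand (see [system_preset()]).
#'
#' @param trimer_extinction,pentamer_extinction Molar absorptivity at 280 nm
#'   per monomer, 1/(M cm).
#' @param trimer_mw,pentamer_mw Monomer mass, kDa.
#' @return A tibble with columns `name`, `oligomer_size`, `copies_complete`,
#'   `monomer_mw`, `extinction`.
#' @export
default_components <- function(trimer_extinction = 20000,
                               pentamer_extinction = 15000,
                               trimer_mw = 15.5, pentamer_mw = 12.9) {
  stopifnot(trimer_extinction > 0, pentamer_extinction > 0)
  tibble::tibble(
    name = c("T", "P"),
    oligomer_size = c(3L, 5L),
    copies_complete = c(20L, 12L),
    monomer_mw = c(trimer_mw, pentamer_mw),
    extinction = c(trimer_extinction, pentamer_extinction)
  )
}

#' @export
print.assembly_architecture <- function(x, ...) {
  cat("<assembly_architecture>\n")
  cat("  trimers:   ", max(x$edges$trimer), " (degree ",
      paste(unique(table(x$edges$trimer)), collapse = "/"), ")\n", sep = "")
  cat("  pentamers: ", max(x$edges$pentamer), " (degree ",
      paste(unique(table(x$edges$pentamer)), collapse = "/"), ")\n", sep = "")
  cat("  heteromeric contacts:", x$total_contacts, "\n")
  invisible(x)
}

#' Species table for the equilibrium model
#'
#' Returns the set of assembly species whose equilibrium concentrations the
#' model evaluates, with the contact count `contacts` (the multiplier of the
#' per-contact energy in the Boltzmann exponent) and the symmetry number
#' `symmetry` (the rotational degeneracy divisor) of each species.
#'
#' The `"simplified"` table contains only the complete 120-subunit assembly
#' T60P60 (60 contacts, symmetry 60) and is appropriate for equimolar inputs,
#' where intermediates do not accumulate. The `"inclusive"` table adds three
#' late intermediates (T60P55, T57P60, T54P60, which co-elute with the complete
#' assembly in the high-MW SEC fraction) and five early intermediates (T6P10,
#' T6P5, T3P15, T3P10, T3P5, which elute late with the free components).
#' Species labels count monomers: T57P60 has 19 trimeric building blocks (57
#' monomers) and 12 pentameric blocks.
#'
#' Contact and symmetry numbers for T60P60, T57P60 and T3P5 follow the model's
#' closed forms; the remaining defaults are the edge counts and rotational
#' orders of the corresponding partial icosahedral structures (e.g. one missing
#' pentamer removes 5 contacts and leaves a C5 axis: T60P55 has 55 contacts,
#' symmetry 5). They can be overridden by passing an edited tibble anywhere a
#' `species` argument is accepted.
#'
#' @param model `"simplified"` or `"inclusive"`.
#' @return A tibble with columns `species_id`, `n_trimers`, `n_pentamers`
#'   (building-block counts), `t_monomers`, `p_monomers`, `contacts`,
#'   `symmetry`, `mw_class` (`"high"` or `"low"`), `role`.
#' @examples
#' species_table("inclusive")
#' @export
species_table <- function(model = c("simplified", "inclusive")) {
  model <- match.arg(model)
  tbl <- tibble::tribble(
    ~species_id, ~n_trimers, ~n_pentamers, ~contacts, ~symmetry, ~mw_class, ~role,
    "T60P60", 20L, 12L, 60L, 60L, "high", "complete",
    "T60P55", 20L, 11L, 55L,  5L, "high", "late_intermediate",
    "T57P60", 19L, 12L, 57L,  3L, "high", "late_intermediate",
    "T54P60", 18L, 12L, 54L,  1L, "high", "late_intermediate",
    "T6P10",   2L,  2L,  3L,  1L, "low",  "early_intermediate",
    "T6P5",    2L,  1L,  2L,  1L, "low",  "early_intermediate",
    "T3P15",   1L,  3L,  3L,  3L, "low",  "early_intermediate",
    "T3P10",   1L,  2L,  2L,  1L, "low",  "early_intermediate",
    "T3P5",    1L,  1L,  1L,  1L, "low",  "early_intermediate"
  )
  tbl <- dplyr::mutate(tbl,
    t_monomers = 3L * .data$n_trimers,
    p_monomers = 5L * .data$n_pentamers,
    .after = "n_pentamers"
  )
  if (model == "simplified") tbl[tbl$role == "complete", ] else tbl
}

#' Maximum number of evenly removable trimeric voids
#'
#' Finds the largest set of trimer nodes that can be deleted from the contact
#' graph such that every pentamer keeps at least `min_contacts` of its 5
#' incident contacts, by depth-first branch-and-bound over face subsets. This
#' quantifies how many trimeric voids a partial assembly can host before some
#' pentamer becomes weakly held.
#'
#' On the icosahedral incidence graph the pure counting criterion admits 8
#' voids at `min_contacts = 3` (two disjoint tetrads of faces); descriptions of
#' this architecture sometimes quote "up to seven" voids, which appears to
#' reflect an additional, unstated placement constraint. This function
#' implements the stated graph criterion only.
#'
#' @param architecture An [i53_architecture()] object.
#' @param min_contacts Integer in 0..5: contacts each pentamer must retain.
#' @return A list with `n_max` (integer) and `witness` (integer vector of
#'   removable trimer indices attaining the maximum).
#' @examples
#' max_trimeric_voids(i53_architecture(), min_contacts = 4)$n_max  # 4
#' @export
max_trimeric_voids <- function(architecture, min_contacts) {
  stopifnot(inherits(architecture, "assembly_architecture"),
            min_contacts >= 0, min_contacts <= 5)
  edges <- architecture$edges
  n_tri <- max(edges$trimer)
  n_pen <- max(edges$pentamer)
  # incidence: pentamers contacted by each trimer
  inc <- split(edges$pentamer, edges$trimer)
  cap <- 5L - as.integer(min_contacts)  # removable edges per pentamer
  if (cap == 0L) return(list(n_max = 0L, witness = integer(0)))

  best <- integer(0)
  used <- integer(n_pen)  # edges removed so far per pentamer
  # upper bound: total remaining pentamer capacity / 3 edges per trimer
  recurse <- function(next_tri, chosen) {
    if (length(chosen) > length(best)) best <<- chosen
    if (next_tri > n_tri) return()
    remaining_capacity <- sum(pmax(cap - used, 0L))
    if (length(chosen) + min(n_tri - next_tri + 1L,
                             remaining_capacity %/% 3L) <= length(best)) {
      return()
    }
    for (i in next_tri:n_tri) {
      pens <- inc[[i]]
      if (all(used[pens] < cap)) {
        used[pens] <<- used[pens] + 1L
        recurse(i + 1L, c(chosen, i))
        used[pens] <<- used[pens] - 1L
      }
    }
  }
  recurse(1L, integer(0))
  list(n_max = length(best), witness = best)
}
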