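---
title: "The equilibrium assembly model and its numerical treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The equilibrium assembly model and its numerical treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icofit)
```

## The system and the model

Two-component I53-class nanomaterials assemble from 20 trimeric and 12
pentameric building blocks into a 120-subunit icosahedron. The trimers sit on
the faces and the pentamers on the vertices of an icosahedron, so every
trimer makes 3 and every pentamer 5 identical heteromeric contacts — 60 in
the complete particle, with no homomeric contacts. `i53_architecture()`
realizes this combinatorially as the face–vertex incidence of the icosahedral
graph; no 3D coordinates are involved anywhere in the package.

Because the building blocks pre-form and only one interface drives assembly,
a hierarchical mass-action treatment applies: the equilibrium concentration
of a species with $a$ trimeric blocks, $b$ pentameric blocks, $c$ contacts
and rotational symmetry number $s$ is

$$[\mathrm{T}_a\mathrm{P}_b] \;=\; \frac{3^a\,5^b}{s}
  \left(\frac{[\mathrm{T}]}{3\times10^6}\right)^{a}
  \left(\frac{[\mathrm{P}]}{5\times10^6}\right)^{b}
  e^{\,c\,|\Delta G_{\mathrm{con}}|/RT},$$

with free subunit concentrations in µM, molar species concentrations, and
$T = 296\,\mathrm{K}$ throughout ($R = 1.98720\times10^{-3}$ kcal/(mol·K)).
The statistical prefactor $3^a 5^b$ counts the ways monomers present as
blocks and $1/s$ removes rotational overcounting of the assembled species.

**Sign convention.** $|\Delta G_{\mathrm{con}}|$ is stored as a positive
magnitude of a *favorable* association energy: larger magnitude, more
assembly. The Boltzmann exponent is therefore $+c\,|\Delta G|/RT$. This is
worth stating prominently because the contact energy is conventionally quoted
as a positive number of kcal/mol for these systems even though the
association free-energy change is negative; the package's monotonicity tests
pin the convention down.

### Species sets

`species_table("simplified")` holds only the complete assembly T60P60
($c=60$, $s=60$) — appropriate near equimolar input, where intermediates do
not accumulate. `species_table("inclusive")` adds the late intermediates
T60P55 ($c=55$, $s=5$), T57P60 ($c=57$, $s=3$), T54P60 ($c=54$, $s=1$) and
the early intermediates T6P10, T6P5, T3P15, T3P10, T3P5, chosen near the
termini of assembly pathways where equilibrium intermediates concentrate.
Contact and symmetry numbers for species not fixed by the closed forms above
are the edge counts and rotational orders of the corresponding partial
icosahedral structures (one missing pentamer deletes 5 contacts and keeps a
C5 axis, etc.). The table is data, not code: pass an edited tibble to any
`species` argument to model other architectures or alternative
intermediate sets.

Late intermediates co-elute with the complete particle in the high-MW SEC
fraction; early intermediates co-elute with free components in the low-MW
fraction. That mw_class split, not the species identity, is what the signal
model sees.

## Numerics

### Log-domain evaluation

At $|\Delta G| = 3.6$ kcal/mol the complete assembly's Boltzmann factor is
$e^{367}$ while its concentration product is $\sim e^{-390}$; neither factor
exists in double precision. All species math therefore stays in natural
logs (`log_species_concentration()`), and totals are formed with
log-sum-exp. A frozen set of 50-digit arbitrary-precision evaluations of the
mass-action law backs this up in the test suite at $10^{-10}$ relative
tolerance, and the no-overflow envelope is tested to $|\Delta G| = 10$
kcal/mol and concentrations down to $10^{-6}$ µM.

### The inverse solver

Experiments fix the input totals $([\mathrm{T}]_0, [\mathrm{P}]_0)$, not the
free concentrations, so `solve_equilibrium()` inverts the mass balance. The
totals are posynomials in the free concentrations; the solver runs
Levenberg–Marquardt on $(\ln[\mathrm{T}], \ln[\mathrm{P}])$ with the
analytic Jacobian (exponent-weighted shares of each term), vectorized over
input points, to a relative mass-balance tolerance of $10^{-9}$. Plain
damped Newton is not enough: when assembly is nearly complete a single
species dominates both totals, the Jacobian rows become parallel, and the
Newton direction is cancellation noise. The adaptive damping degrades
gracefully to scaled gradient steps there. Any point still unconverged (this
occurs only at extreme energies, $\gtrsim 8$ kcal/mol) is finished by nested
bisection, which needs nothing but the monotonicity of each log-total in its
own variable and is unconditionally convergent; positivity of the Jacobian
determinant (Cauchy–Schwarz plus the free-monomer diagonal) guarantees the
outer bisection's monotonicity and the uniqueness of the solution. Inputs
with a zero total return the all-free state, since every modeled species
contains both components.

### Forward grids, slicing and binning

`forward_grid()` evaluates the closed form over a free-concentration grid —
this is the parameterization in which the model's 3D partition surfaces are
drawn — and `slice_and_bin()` cuts those surfaces to 2D curves: points
within half a 1 µM slab of the plane of interest (equimolar, or constant
component at 50 µM) are retained and averaged in bins of the in-plane
coordinate (0.5 µM default; 0.0625 µM for the steeper I53-50 equimolar fit,
via `system_preset()`). The fitting path predicts directly at the
experimental totals with the inverse solver instead — equivalent by the
conservation guarantee and free of binning artifacts — while the binning
path is retained for figure reproduction.

## From concentrations to SEC signals

Predicted signals mirror the experimental normalization: the high-MW signal
is the extinction-weighted high-MW monomer content relative to the expected
signal of complete nanomaterial at 50 µM of each component, and the low-MW
signal is the analogous ratio times the adjustment factor $F_{A280}$
(`predict_normalized_signals()`, `signal_factors()`). $F_{A280}$ — about
0.89 for I53-40 and 0.90 for I53-50 — absorbs the ~10% excess A280 of
assembled material attributed to scattering; no separate optical model is
attempted, exactly as in the reference analysis. Experimentally it is the
ratio of mean summed component-injection signal to mean summed assembled-run
signal (`adjustment_factor()`), with uncertainty from replicate scatter via
the first-order ratio formula (`propagate_sd()`).

`normalize_peak_areas()` applies the two-denominator convention: assembled
peak areas over the mean total signal of the equimolar 50 µM reference
assemblies (six in the reference design), residual-component areas over the
sum of the two separate 50 µM component injections. Normalization is
deliberately not idempotent — a second call errors rather than silently
rescaling.

## Fitting the contact energy

`fit_dgcon()` scans $|\Delta G_{\mathrm{con}}|$ over 2.5–5.5 kcal/mol in
0.01 steps by default: the scan brackets per-contact energies reported for
cooperatively assembling icosahedral architectures, and the step is an order
of magnitude finer than the ±0.25 kcal/mol band conventionally drawn around
such fits. At each candidate energy the model predicts both normalized
signals at every experimental concentration pair (replicates averaged
first); the objective is the pooled root mean squared percent error,
asymmetric by definition (experimental value in the denominator), with
zero-valued observations dropped as their percent error is undefined.
Equimolar and cooperativity series are pooled into one objective by default;
fitting them separately is a matter of subsetting the input. Reference
injections are calibration standards and are excluded from the objective.
For systems that assemble aberrantly with super-stoichiometric pentamer, the
`"t0_ge_p0"` restriction drops that regime before fitting (applied
automatically by the I53-50 preset). A minimum on the scan boundary or a
flat profile is warned about rather than silently returned.

The package quantifies fit uncertainty only through the ±0.25 kcal/mol
visualization band and seeded parameter-recovery experiments (noisy
synthetic data; median recovery error well under the scan step) — no
asymptotic standard errors are attempted, since the objective is a pooled
percent error over heteroscedastic observations.

## Cooperativity statistics

`mass_fraction_from_peaks()` converts normalized equimolar peak areas to the
assembled mass fraction $\Theta = \mathrm{high}/(\mathrm{high} +
\mathrm{low}/F_{A280})$ and to molar amounts assuming equimolar
stoichiometry in both fractions. `hill_analysis()` regresses
$\log_{10}(\Theta/(1-\Theta))$ on $\log_{10} L$; the slope is the Hill
coefficient and the back-transformed x-intercept the apparent $K_D$. Three
choices here were genuinely open and are configurable:

* **Inclusion band.** Points with $0.05 < \Theta < 0.95$ enter the
  regression by default; outside that band the logit is dominated by
  measurement noise. No inclusion rule is stated for the reference analysis.
* **Definition of $L$.** Total residual monomer (both components' low-MW
  monomer equivalents, µM); the reference figures say only "free
  components".
* **Base-10 logs**, the field convention; the slope is base-invariant.

$\Theta$ is monomer-count weighted by default; a mass-weighted basis is
available in `mass_fraction_assembled()` and matters only when the monomer
MWs differ appreciably.

`chevron_summary()` tabulates normalized signals per variable-component
concentration with replicate-and-reference-propagated error bars and the
theoretical-yield line (quantitative incorporation of the limiting
component); in a cooperative system the residual-component signal traces a V
with its minimum at equimolar input.

## Thermal callers

Two empirical callers, deliberately model-free:

* `tm_by_derivative()` — local-quadratic interpolation of the trace onto a
  0.1 °C grid, central-difference derivative, Tm at the derivative extremum
  in the transition direction. The quadratic interpolant is a hand-rolled
  3-point Lagrange stencil (no installed interpolator exposes quadratic
  splines); the caller is affine-invariant in the signal and refuses traces
  whose derivative peak is indistinct from the baseline (ratio to the median
  below 2 by default). Accuracy is bounded by the interpolation grid:
  ±0.1 °C on 1 °C-sampled logistics.
* `t_by_threshold()` — a threshold line with slope equal to the pooled
  baseline drift (`baseline_drift()`: mean initial-region least-squares
  slope per curve, pooled per assay, overridable per curve) and intercept a
  stated fraction of a typical endpoint magnitude above the starting signal;
  the call is the first crossing (onset semantics) of the cubic-spline
  interpolated trace, refined linearly between grid points. Presets:
  SLS 20% of 60,000 counts; nanoDSF 50% of −4.5 nm or 20% of −14.2 nm; CD
  20% of a system-specific ellipticity loss that must be supplied
  (`threshold_spec("cd_i53_50", endpoint_magnitude = ...)`).

`initial_rate()` is ordinary least squares on a 100–200 s window of a
coupled-assay absorbance trace, optionally relative to a control slope. No
two-state thermodynamic unfolding fits are attempted; the callers are
empirical by design.

## The synthetic-data generator

The generator exists so every analysis stage is testable without instrument
data, and its defaults are the reference study's conditions: constant
component at 50 µM with the other at 12.5–150 µM (0.25:1–3:1) in two series,
equimolar series spanning the pseudo-critical region, 3 technical replicates,
six 50 µM reference assemblies, separate component injections. Peak areas are
extinction-weighted monomer signals from the solved model; the assembled peak
carries a $1/F_{A280}$ scattering excess and the residual peak the
$F_{A280}$ convention of the signal model, so the simulated data are exactly
self-consistent with the analysis chain — a noiseless dataset round-trips the
generating energy to the scan step, which is the property the recovery tests
lean on.

Replicate noise is multiplicative lognormal with unit mean at cv 5% by
default. The choice of multiplicative over additive noise is not derivable
from the reference data; the magnitude is loosely calibrated to the reported
adjustment-factor scatter (0.06/0.89 ≈ 7%, 0.04/0.90 ≈ 4%). Identical seeds
give byte-identical datasets.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: reference injections are idealized as fully
assembled (real references contain a little residual free component, which
perturbs the normalization denominator by a few percent); there are no
off-pathway architectures, no kinetic trapping, no baseline or integration
artifacts in the synthetic chromatograms, and no assembly kinetics at all.
The observed failure of real I53-50 data to match the equilibrium model in
the excess-pentamer regime is kinetic in origin and is intentionally outside
the model's scope.

`sim_chromatogram()`/`integrate_chromatogram()` render solved states as
Gaussian-peak traces on a 24 mL column (assembled ≈ 12 mL, components ≈ 16
mL) and recover areas by the trapezoidal rule within 1% for
baseline-separated peaks; `sim_melt_curve()` produces logistic transitions
with linear drift and seeded Gaussian noise at assay-typical scales.

## Architecture side results

`max_trimeric_voids()` answers a topological question about partial
assemblies: how many trimer faces can be removed while every pentamer keeps
at least a floor of its 5 contacts. Branch-and-bound over face subsets
(verified against exhaustive enumeration in the tests) gives 0, 4 and 8
voids for floors of 5, 4 and 3 contacts. Descriptions of this architecture
sometimes state that up to *seven* voids can be "evenly distributed" at the
3-contact floor; the pure counting criterion admits 8 (two disjoint tetrads
of faces), so the quoted 7 evidently encodes an additional placement
constraint that is not spelled out. The function implements the stated graph
criterion and documents the tension rather than guessing the constraint.

## Problem sizes and limitations

The test suite exercises the solver on 100-point random concentration grids
per energy, fits 20 seeded noisy datasets (truths 3.4/3.6/4.1 kcal/mol) for
parameter recovery, and verifies the log-domain math against frozen 50-digit
references; the whole suite runs in about five minutes on one core. Known
limitations: equilibrium only (no nucleation, growth or curing kinetics);
default extinction coefficients and monomer masses are synthetic
placeholders to be replaced with measured values; the species set, while
extensible, inherits the "termini of assembly pathways" heuristic rather
than enumerating all partial structures; and the model's cooperativity
(noiseless Hill slopes of model curves) is substantially steeper than
experimentally observed Hill coefficients, so fitted contact energies —
not Hill slopes — are the model's quantitative point of contact with data.
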