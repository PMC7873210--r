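# Independent oracles used across the suite. These deliberately avoid the
# package's log-domain code paths.

# Scalar bisection on the simplified-model mass balance at equimolar input:
# t0 = 60e6 * [T60P60] + [T] with [T] = [P]. Valid for moderate contact
# energies where the direct double-precision evaluation cannot overflow.
oracle_equimolar_massfrac <- function(total_uM, dg, R = 1.98720e-3, TK = 296) {
  E <- 60 * dg / (R * TK)
  t0_of <- function(Tf) {
    60e6 * exp(32 * log(Tf * 1e-6) + E - log(60)) + Tf
  }
  lo <- 0
  hi <- total_uM
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (t0_of(mid) > total_uM) hi <- mid else lo <- mid
  }
  (total_uM - (lo + hi) / 2) / total_uM
}

# Exhaustive search over all k-subsets of trimer faces: the largest k such
# that some subset removes at most (5 - min_contacts) edges from every
# pentamer.
oracle_max_voids <- function(edges, min_contacts, kmax = 8L) {
  n_tri <- max(edges$trimer)
  n_pen <- max(edges$pentamer)
  M <- matrix(0L, n_tri, n_pen)
  M[cbind(edges$trimer, edges$pentamer)] <- 1L
  cap <- 5L - min_contacts
  if (cap == 0L) return(0L)
  best <- 0L
  for (k in seq_len(kmax)) {
    combs <- utils::combn(n_tri, k)
    ind <- matrix(0L, n_tri, ncol(combs))
    ind[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = k))] <- 1L
    removed <- crossprod(M, ind)  # pentamer x subset: edges removed
    feasible <- colSums(removed > cap) == 0L
    if (!any(feasible)) break
    best <- k
  }
  best
}

# Frozen 50-digit arbitrary-precision evaluations of the per-species
# mass-action law, ln concentration in M at (species, free_t uM, free_p uM,
# dG_con kcal/mol) with R = 1.98720e-3 kcal/(mol K), T = 296 K.
frozen_log_conc_oracle <- list(
  list("T6P5", 4.1376, 20.2698, 4.093, -21.68039773018454665261),
  list("T3P5", 25.8152, 20.7989, 0.522, -20.45772120010696610444),
  list("T3P10", 26.8227, 34.1094, 5.501, -12.39397099506830556077),
  list("T3P5", 23.9567, 6.1302, 4.271, -15.38054829541890562646),
  list("T60P55", 21.6302, 34.0038, 3.095, -40.22290677597358658456),
  list("T6P10", 37.5197, 38.0653, 0.81, -36.60253455045951244832),
  list("T6P5", 36.857, 2.6019, 0.952, -30.03926602197816746472),
  list("T6P10", 19.9166, 9.7719, 6.014, -14.0472569300908814791),
  list("T6P10", 25.5003, 0.7543, 1.249, -42.97843110070872472836),
  list("T3P5", 34.0196, 0.8887, 7.075, -12.19408717847757558841)
)
# ln of the complete-assembly concentration at 5/5 uM free, dG_con = 3.6
frozen_log_conc_t60p60_5_5_36 <- -27.473628091103053684
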