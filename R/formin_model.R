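# Closed-form barbed-end kinetic model: open/closed FH2 equilibrium,
# elongation, and the two-route (open-state + transition-state) global
# dissociation rate with Bell-type force dependence and profilin protection.

#' Actin subunit size
#'
#' Length added to a filament per incorporated subunit, in nanometres
#' (about 370 subunits per micrometre). Used for all length/velocity
#' conversions in the package.
#' @export
SUBUNIT_NM <- 2.7

#' Kinetic parameters of a formin construct
#'
#' Bundles every rate constant and working distance of the barbed-end model
#' for one formin construct (e.g. mDia1 FH1-FH2-DAD, FH2-DAD, mDia2).
#'
#' @param k_on subunit association rate from the open state, per uM per s.
#' @param K_co dimensionless closed:open equilibrium constant at zero force
#'   (larger values favour the elongation-forbidding closed state).
#' @param k_offO0 open-state dissociation rate at zero force, per s.
#' @param k_offT0 transition-state dissociation rate at zero force, per s.
#' @param k_decay decay rate of the post-addition transition state back into
#'   the open/closed rapid equilibrium, per s.
#' @param delta_O working distance of the open-state dissociation route, nm.
#' @param delta_T working distance of the transition-state route, nm.
#' @param delta_step working distance of the open/closed equilibrium, nm;
#'   defaults to one monomer size (`SUBUNIT_NM`).
#' @param K_PB effective profilin affinity for the barbed end from solution,
#'   uM; solution-bound profilin pauses elongation and gates the open route.
#' @param K_ring effective profilin scale of FH1-mediated barbed-end occupancy
#'   (the "ring complex"), uM; gates only the transition route.
#' @param fh1_boost_max maximal FH1-mediated enhancement of subunit delivery
#'   (dimensionless); forced to 0 when `has_FH1 = FALSE`.
#' @param K_boost profilin scale of the delivery enhancement, uM.
#' @param has_FH1 logical; `FALSE` for FH2-DAD constructs lacking FH1 domains.
#' @param salt_multiplier,label_multiplier dimensionless multipliers applied
#'   to both zero-force dissociation rates, calibrated per ionic strength and
#'   actin labeling fraction.
#'
#' @return An object of class `formin_params` (a validated named list).
#' @seealso [conditions()], [dissociation_rate()], [formin_presets()]
#' @examples
#' p <- formin_params(k_on = 22, k_offO0 = 2e-4, k_offT0 = 3, k_decay = 1e5)
#' dissociation_rate(conditions(actin = 1), f = 0, p)
#' @export
formin_params <- function(k_on = 22, K_co = 1, k_offO0 = 2e-4, k_offT0 = 3,
                          k_decay = 1e5, delta_O = 2.7, delta_T = 0.8,
                          delta_step = SUBUNIT_NM, K_PB = 30, K_ring = 0.05,
                          fh1_boost_max = 8, K_boost = 0.5, has_FH1 = TRUE,
                          salt_multiplier = 1, label_multiplier = 1) {
  p <- list(k_on = k_on, K_co = K_co, k_offO0 = k_offO0, k_offT0 = k_offT0,
            k_decay = k_decay, delta_O = delta_O, delta_T = delta_T,
            delta_step = delta_step, K_PB = K_PB, K_ring = K_ring,
            fh1_boost_max = fh1_boost_max, K_boost = K_boost,
            has_FH1 = isTRUE(has_FH1),
            salt_multiplier = salt_multiplier,
            label_multiplier = label_multiplier)
  if (!p$has_FH1) p$fh1_boost_max <- 0
  validate_formin_params(p)
  class(p) <- "formin_params"
  p
}

validate_formin_params <- function(p) {
  num <- c("k_on", "K_co", "k_offO0", "k_offT0", "k_decay", "delta_O",
           "delta_T", "delta_step", "K_PB", "K_ring", "fh1_boost_max",
           "K_boost", "salt_multiplier", "label_multiplier")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("formin_params: field '", f, "' must be a finite numeric scalar")
    if (v < 0) stop("formin_params: field '", f, "' must be >= 0")
  }
  if (p$K_co <= 0) stop("formin_params: K_co must be > 0")
  if (p$K_PB <= 0 || p$K_ring <= 0 || p$K_boost <= 0)
    stop("formin_params: affinity constants must be > 0")
  if (!p$has_FH1 && p$fh1_boost_max != 0)
    stop("formin_params: has_FH1 = FALSE requires fh1_boost_max = 0")
  invisible(p)
}

#' Solution conditions
#'
#' Solution composition and thermal energy for a model evaluation or a
#' simulated experiment.
#'
#' @param actin total G-actin concentration, uM.
#' @param profilin profilin concentration, uM.
#' @param kcl KCl concentration, mM (bookkeeping only; ionic-strength effects
#'   enter the model through `salt_multiplier` in [formin_params()]).
#' @param labeling_fraction fraction of fluorescently labeled actin in [0, 1]
#'   (bookkeeping only; enters through `label_multiplier`).
#' @param kBT thermal energy, pN nm. Default 4.11 (25 C); room-temperature
#'   experiments at 19-23 C correspond to 4.03-4.09.
#'
#' @return An object of class `conditions`.
#' @export
conditions <- function(actin = 1, profilin = 0, kcl = 100,
                       labeling_fraction = 0, kBT = 4.11) {
  cn <- list(actin = actin, profilin = profilin, kcl = kcl,
             labeling_fraction = labeling_fraction, kBT = kBT)
  for (f in names(cn)) {
    v <- cn[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("conditions: field '", f, "' must be a finite non-negative scalar")
  }
  if (cn$labeling_fraction > 1)
    stop("conditions: labeling_fraction must be <= 1")
  if (cn$kBT <= 0) stop("conditions: kBT must be > 0")
  class(cn) <- "conditions"
  cn
}

#' Bell force-dependent rate
#'
#' Slip-bond rate law `k(f) = k0 * exp(f * delta / kBT)`: a transition rate
#' accelerated exponentially by force, with working distance `delta`.
#'
#' @param k0 zero-force rate, per s.
#' @param delta working distance, nm.
#' @param f applied force, pN (vectorised).
#' @param kBT thermal energy, pN nm.
#' @return Rate(s) per s; monotone non-decreasing in `f`.
#' @examples
#' bell_rate(0.1, delta = 2.7, f = 1.522, kBT = 4.11) # ~ 0.1 * e
#' @export
bell_rate <- function(k0, delta, f, kBT = 4.11) {
  if (!all(is.finite(k0), is.finite(delta), is.finite(f), is.finite(kBT)))
    stop("bell_rate: non-finite input")
  if (kBT <= 0) stop("bell_rate: kBT must be > 0")
  if (k0 < 0 || delta < 0 || any(f < 0))
    stop("bell_rate: k0, delta and f must be >= 0")
  x <- f * delta / kBT
  if (any(x > 700)) stop("bell_rate: f*delta/kBT > 700 is unphysical (overflow)")
  k0 * exp(x)
}

#' Open-state occupancy of the FH2 dimer
#'
#' Probability that the rapid open/closed conformational equilibrium sits in
#' the elongation-competent open state, `1 / (1 + K_co * exp(-f*delta_step/kBT))`.
#' Tension tilts the equilibrium towards the open state over a working
#' distance of one monomer size.
#'
#' @param f force, pN (vectorised).
#' @param params a [formin_params()] object.
#' @param kBT thermal energy, pN nm.
#' @return Probability in (0, 1], non-decreasing in `f`.
#' @export
p_open <- function(f, params, kBT = 4.11) {
  stopifnot(all(f >= 0))
  1 / (1 + params$K_co * exp(-f * params$delta_step / kBT))
}

#' Profilin occupancy of the barbed end
#'
#' Two effective occupancies: `pi_solution`, profilin bound at the barbed end
#' from solution (pauses elongation, gates the open dissociation route for all
#' constructs), and `pi_fh1`, profilin held at the barbed end by an FH1
#' polyproline track as a "ring complex" (gates only the transition route;
#' zero without FH1 domains).
#'
#' @param conds a [conditions()] object.
#' @param params a [formin_params()] object.
#' @return Named list with `pi_solution` and `pi_fh1`, both in [0, 1).
#' @export
profilin_occupancy <- function(conds, params) {
  prf <- conds$profilin
  pi_solution <- prf / (prf + params$K_PB)
  pi_fh1 <- if (params$has_FH1) prf / (prf + params$K_ring) else 0
  list(pi_solution = pi_solution, pi_fh1 = pi_fh1)
}

fh1_boost <- function(profilin, params) {
  if (!params$has_FH1) return(0)
  params$fh1_boost_max * profilin / (profilin + params$K_boost)
}

#' Barbed-end elongation rate
#'
#' `v = p_open(f) * k_on * [actin] * (1 + boost(profilin)) * (1 - pi_solution)`
#' in subunits per second. Linear in actin at fixed profilin; biphasic in
#' profilin for FH1-bearing constructs (FH1 delivery accelerates elongation at
#' low profilin, solution-route barbed-end occupancy slows it at high
#' profilin).
#'
#' @inheritParams profilin_occupancy
#' @param f force, pN (vectorised).
#' @return Elongation rate, subunits per s.
#' @export
elongation_rate <- function(conds, f, params) {
  occ <- profilin_occupancy(conds, params)
  p_open(f, params, conds$kBT) * params$k_on * conds$actin *
    (1 + fh1_boost(conds$profilin, params)) * (1 - occ$pi_solution)
}

#' Global formin dissociation rate and its two routes
#'
#' Evaluates the full model at given conditions and force(s). The global
#' dissociation rate is the sum of two routes:
#' \describe{
#'   \item{open route}{`p_open(f) * k_offO(f)`, with `k_offO(f)` a Bell rate
#'     of working distance `delta_O`; dissociation from the open state
#'     during the open/closed equilibrium. Solution profilin on the barbed
#'     end pauses elongation but does not shield the FH2 dimer, so this
#'     route is not gated by `pi_solution`; with `pi_fh1 = 0` the global
#'     rate at fixed force is then a function of the elongation rate alone,
#'     however that rate was reached (the FH2-only collapse).}
#'   \item{transition route}{`v_elong * p_T(f) * (1 - pi_fh1)`, where
#'     `p_T = k_offT / (k_offT + k_decay)` is the per-addition probability of
#'     dissociating from the short-lived transition state entered after each
#'     subunit addition, and `k_offT(f)` is a Bell rate of working distance
#'     `delta_T`. Proportional to the elongation rate, hence to actin
#'     concentration; protected by FH1-held profilin.}
#' }
#' Salt and labeling multipliers scale both zero-force dissociation rates.
#'
#' @inheritParams elongation_rate
#' @return A data frame (class `formin_prediction`) with one row per force:
#'   `f`, `v_elong` (subunits/s), `k_off`, `k_off_open_route`,
#'   `k_off_transition_route` (per s), `p_open`, `pi_solution`, `pi_fh1`.
#' @examples
#' p <- formin_params()
#' dissociation_rate(conditions(actin = 1, profilin = 5), f = c(0, 2, 4), p)
#' @export
dissociation_rate <- function(conds, f, params) {
  stopifnot(all(f >= 0))
  mult <- params$salt_multiplier * params$label_multiplier
  occ <- profilin_occupancy(conds, params)
  po <- p_open(f, params, conds$kBT)
  v <- elongation_rate(conds, f, params)
  k_open <- po *
    bell_rate(params$k_offO0 * mult, params$delta_O, f, conds$kBT)
  k_T <- bell_rate(params$k_offT0 * mult, params$delta_T, f, conds$kBT)
  p_T <- k_T / (k_T + params$k_decay)
  k_trans <- v * p_T * (1 - occ$pi_fh1)
  out <- data.frame(f = f, v_elong = v, k_off = k_open + k_trans,
                    k_off_open_route = k_open,
                    k_off_transition_route = k_trans,
                    p_open = po, pi_solution = occ$pi_solution,
                    pi_fh1 = occ$pi_fh1)
  class(out) <- c("formin_prediction", "data.frame")
  out
}

#' Mean filament length at steady dissociation
#'
#' Expected filament length produced before formin dissociation: elongation
#' rate divided by dissociation rate, converted to micrometres with 2.7 nm
#' per subunit. Because force increases `k_off` much faster than `v_elong`,
#' this length collapses steeply with tension.
#'
#' @inheritParams elongation_rate
#' @return Mean length(s) in um; `Inf` where `k_off = 0` (a formin that never
#'   dissociates grows without bound).
#' @export
mean_filament_length <- function(conds, f, params) {
  pred <- dissociation_rate(conds, f, params)
  len <- ifelse(pred$k_off == 0, Inf,
                pred$v_elong / pred$k_off * (SUBUNIT_NM / 1000))
  len
}

#' Family of k_off(f) curves across actin concentrations
#'
#' Evaluates the dissociation rate over a force grid for several actin
#' concentrations and classifies the force regime. When the open route has
#' the larger working distance it takes over at high force and the curves for
#' different actin concentrations converge ("converging" regime); when the
#' transition route keeps the larger working distance the curves remain
#' separated ("separated" regime). The classifier compares the max/min ratio
#' of `k_off` across concentrations at the lowest versus the highest force of
#' the grid; ties classify as "separated".
#'
#' @param actin_list two or more actin concentrations, uM.
#' @param f_grid increasing force grid, pN.
#' @param conditions_base a [conditions()] object supplying everything but
#'   actin.
#' @param params a [formin_params()] object.
#' @return List with `curves` (data frame: actin, f, k_off), `ratio_low`,
#'   `ratio_high` (max/min across concentrations at the grid ends) and
#'   `regime` ("converging" or "separated").
#' @export
koff_force_family <- function(actin_list, f_grid, conditions_base, params) {
  if (length(actin_list) < 2L)
    stop("koff_force_family: need at least 2 actin concentrations")
  if (is.unsorted(f_grid))
    stop("koff_force_family: f_grid must be increasing")
  curves <- do.call(rbind, lapply(actin_list, function(a) {
    cn <- conditions_base
    cn$actin <- a
    pred <- dissociation_rate(cn, f_grid, params)
    data.frame(actin = a, f = f_grid, k_off = pred$k_off)
  }))
  ratio_at <- function(fv) {
    k <- curves$k_off[curves$f == fv]
    max(k) / min(k)
  }
  ratio_low <- ratio_at(f_grid[1L])
  ratio_high <- ratio_at(f_grid[length(f_grid)])
  regime <- if (ratio_high < ratio_low) "converging" else "separated"
  list(curves = curves, ratio_low = ratio_low, ratio_high = ratio_high,
       regime = regime)
}

#' Preset parameter sets
#'
#' Illustrative calibrations for the constructs studied with this model:
#' `mDia1` (full FH1-FH2-DAD), `mDia1_FH1_2PP` (truncated FH1 with two
#' polyproline tracks: weaker delivery boost, weaker ring protection),
#' `mDia1_FH2` (FH2-DAD only, no FH1), and `mDia2` (slower elongation, far
#' more processive). Values reproduce the qualitative behaviour of each
#' construct; they are not fitted constants.
#'
#' @return Named list of [formin_params()] objects.
#' @export
formin_presets <- function() {
  list(
    mDia1 = formin_params(),
    mDia1_FH1_2PP = formin_params(fh1_boost_max = 5, K_ring = 0.2),
    mDia1_FH2 = formin_params(has_FH1 = FALSE, fh1_boost_max = 0),
    mDia2 = formin_params(k_on = 6, k_offO0 = 2e-5, k_offT0 = 0.4)
  )
}

#' Export model predictions as a tidy table
#'
#' Evaluates the model over a grid of conditions and forces and returns (or
#' writes) a tidy table, one row per combination.
#'
#' @param params a [formin_params()] object.
#' @param construct label recorded in the output.
#' @param actin,profilin,kcl,force vectors defining the evaluation grid.
#' @param kBT thermal energy, pN nm.
#' @param path optional CSV path; when given the table is also written.
#' @return Data frame with columns construct, actin_uM, profilin_uM, kcl_mM,
#'   force_pN, v_elong_sub_s, koff_s, route_open_s, route_transition_s.
#' @export
predict_table <- function(params, construct = "formin", actin = 1,
                          profilin = 0, kcl = 100, force = 0, kBT = 4.11,
                          path = NULL) {
  grid <- expand.grid(actin_uM = actin, profilin_uM = profilin, kcl_mM = kcl,
                      force_pN = force, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cn <- conditions(actin = grid$actin_uM[i], profilin = grid$profilin_uM[i],
                     kcl = grid$kcl_mM[i], kBT = kBT)
    pred <- dissociation_rate(cn, grid$force_pN[i], params)
    cbind(construct = construct, grid[i, , drop = FALSE],
          v_elong_sub_s = pred$v_elong, koff_s = pred$k_off,
          route_open_s = pred$k_off_open_route,
          route_transition_s = pred$k_off_transition_route)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
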