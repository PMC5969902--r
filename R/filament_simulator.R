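# Exact stochastic (event-driven) simulation of single formin-bound
# filaments.  The C++ core handles one constant-condition stretch; the R
# layer assembles protocols, populations and traces.

#' Force protocol for simulated filaments
#'
#' Describes how force is applied to a formin-filament link during a
#' simulation.
#'
#' @param mode `"zero"` (unanchored formin, no force), `"constant"` (fixed
#'   force `f_const`), or `"length_proportional"` (microfluidic drag: the
#'   anchoring-point force is `kappa * L(t)` for current filament length
#'   `L(t)`, re-evaluated after every event).
#' @param f_const constant force, pN.
#' @param kappa drag coefficient, pN per um of filament.
#' @param L0 mean initial filament length, um (required > 0 in
#'   length-proportional mode).
#' @param L0_cv coefficient of variation of initial lengths across a
#'   population (log-normal dispersion; 0 = identical lengths).
#' @return An object of class `force_protocol`.
#' @export
force_protocol <- function(mode = c("zero", "constant", "length_proportional"),
                           f_const = 0, kappa = 0, L0 = 1, L0_cv = 0.2) {
  mode <- match.arg(mode)
  if (f_const < 0) stop("force_protocol: f_const must be >= 0")
  if (kappa < 0) stop("force_protocol: kappa must be >= 0")
  if (L0_cv < 0) stop("force_protocol: L0_cv must be >= 0")
  if (mode == "length_proportional" && L0 <= 0)
    stop("force_protocol: L0 must be > 0 in length_proportional mode")
  structure(list(mode = mode, f_const = f_const, kappa = kappa,
                 L0 = L0, L0_cv = L0_cv),
            class = "force_protocol")
}

# Collapse model parameters + conditions to the scalar rates the core needs.
core_args <- function(params, conds) {
  occ <- profilin_occupancy(conds, params)
  mult <- params$salt_multiplier * params$label_multiplier
  list(
    k_add0 = params$k_on * conds$actin *
      (1 + fh1_boost(conds$profilin, params)) * (1 - occ$pi_solution),
    K_co = params$K_co, delta_step = params$delta_step,
    k_offO0eff = params$k_offO0 * mult,
    delta_O = params$delta_O,
    k_offT0eff = params$k_offT0 * mult, delta_T = params$delta_T,
    k_decay = params$k_decay, pi_fh1 = occ$pi_fh1, kBT = conds$kBT)
}

run_core <- function(params, conds, protocol, t0, L0, horizon,
                     record, transition_mode) {
  a <- core_args(params, conds)
  mode_code <- match(protocol$mode,
                     c("zero", "constant", "length_proportional")) - 1L
  sim_filament_cpp(a$k_add0, a$K_co, a$delta_step, a$k_offO0eff, a$delta_O,
                   a$k_offT0eff, a$delta_T, a$k_decay, a$pi_fh1, a$kBT,
                   mode_code, protocol$f_const, protocol$kappa,
                   t0, L0, horizon, record,
                   identical(transition_mode, "explicit"))
}

#' Simulate one formin-bound filament
#'
#' Statistically exact realisation of the barbed-end model: subunit
#' additions arrive from the instantaneous elongation rate, each addition
#' triggers a transition-state dissociation trial with probability
#' `p_T(f) * (1 - pi_fh1)`, and open-route dissociation runs as a competing
#' exponential clock gated by the open-state occupancy. In
#' length-proportional mode the force `kappa * L` is re-evaluated after
#' every event.
#'
#' @param params a [formin_params()] object.
#' @param conds a [conditions()] object.
#' @param protocol a [force_protocol()] object.
#' @param horizon observation horizon, s; filaments still formin-bound at the
#'   horizon are censored.
#' @param seed integer seed (reproducible: same seed, same trace). `NULL`
#'   continues the current RNG stream.
#' @param L0 initial length, um; defaults to `protocol$L0`.
#' @param record keep the full event trajectory (times/lengths)? Set `FALSE`
#'   for large populations where only lifetimes are needed.
#' @param transition_mode `"instant"` resolves each post-addition transition
#'   state as an instantaneous Bernoulli trial (the transition state decays
#'   fast relative to additions); `"explicit"` additionally draws the dwell
#'   time in the transition state from its exit rate `k_offT(f) + k_decay`,
#'   for sensitivity checks at finite `k_decay`.
#' @return An object of class `filament_trace`: list with `event_times`,
#'   `lengths` (um, at each event), `dissociation_time` (s; `NA` if
#'   censored), `dissociation_route` (`"open"`, `"transition"`, or
#'   `"censored"`), `final_length`, `horizon`, `seed`.
#' @examples
#' tr <- simulate_filament(formin_params(), conditions(actin = 1),
#'                         force_protocol("zero"), horizon = 500, seed = 1)
#' tr$dissociation_route
#' @export
simulate_filament <- function(params, conds, protocol, horizon, seed = NULL,
                              L0 = protocol$L0, record = TRUE,
                              transition_mode = c("instant", "explicit")) {
  transition_mode <- match.arg(transition_mode)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("simulate_filament: horizon must be > 0")
  validate_formin_params(params)
  if (!is.null(seed)) set.seed(seed)
  res <- run_core(params, conds, protocol, 0, L0, horizon,
                  record, transition_mode)
  new_filament_trace(res, horizon, seed)
}

new_filament_trace <- function(res, horizon, seed) {
  route <- c("censored", "open", "transition")[res$route + 1L]
  structure(list(
    event_times = res$event_times,
    lengths = res$lengths,
    dissociation_time = if (res$dissociated) res$t_end else NA_real_,
    dissociation_route = route,
    final_length = res$L_end,
    horizon = horizon,
    seed = seed), class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat("<filament_trace> ",
      if (is.na(x$dissociation_time)) {
        sprintf("censored at %.1f s", x$horizon)
      } else {
        sprintf("dissociated at %.1f s (%s route)",
                x$dissociation_time, x$dissociation_route)
      },
      sprintf(", final length %.2f um\n", x$final_length), sep = "")
  invisible(x)
}

#' Simulate a population of filaments
#'
#' Runs `n` independent filaments. Per-filament RNG substreams are derived
#' deterministically from the population seed, and in length-proportional
#' mode per-filament initial lengths are drawn log-normal with mean
#' `protocol$L0` and coefficient of variation `protocol$L0_cv`.
#'
#' @inheritParams simulate_filament
#' @param n number of filaments (>= 1).
#' @param seed population seed, integer.
#' @return An object of class `filament_population`: list of
#'   [simulate_filament()] traces, with the design stored as attributes.
#' @seealso [population_summary()]
#' @export
simulate_population <- function(n, params, conds, protocol, horizon,
                                seed = 1L, record = TRUE,
                                transition_mode = c("instant", "explicit")) {
  transition_mode <- match.arg(transition_mode)
  if (!is.numeric(n) || n < 1) stop("simulate_population: n must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  L0s <- if (protocol$mode == "length_proportional" && protocol$L0_cv > 0) {
    sdlog <- sqrt(log(1 + protocol$L0_cv^2))
    stats::rlnorm(n, meanlog = log(protocol$L0) - sdlog^2 / 2, sdlog = sdlog)
  } else rep(protocol$L0, n)
  traces <- lapply(seq_len(n), function(i) {
    simulate_filament(params, conds, protocol, horizon,
                      seed = child_seeds[i], L0 = L0s[i], record = record,
                      transition_mode = transition_mode)
  })
  structure(traces, class = "filament_population",
            seed = seed, protocol = protocol, horizon = horizon)
}

#' Per-filament summary of a simulated population
#'
#' @param pop a [simulate_population()] result.
#' @return Data frame with one row per filament: `filament_id`,
#'   `dissociation_time` (NA if censored), `route`, `initial_length_um`,
#'   `final_length_um`, `censored`.
#' @export
population_summary <- function(pop) {
  stopifnot(inherits(pop, "filament_population"))
  do.call(rbind, lapply(seq_along(pop), function(i) {
    tr <- pop[[i]]
    data.frame(filament_id = i,
               dissociation_time = tr$dissociation_time,
               route = tr$dissociation_route,
               initial_length_um = if (!is.null(tr$lengths))
                 tr$lengths[1L] else NA_real_,
               final_length_um = tr$final_length,
               censored = is.na(tr$dissociation_time))
  }))
}

#' Filament length at a given time
#'
#' Piecewise-constant interpolation of a recorded trace (length changes only
#' at addition events).
#' @param trace a recorded [simulate_filament()] trace.
#' @param t time(s), s; must lie within the trace domain.
#' @return Length(s), um.
#' @export
length_at <- function(trace, t) {
  stopifnot(inherits(trace, "filament_trace"))
  if (is.null(trace$event_times))
    stop("length_at: trace was simulated with record = FALSE")
  t_end <- if (is.na(trace$dissociation_time)) trace$horizon
           else trace$dissociation_time
  if (any(t < 0 | t > t_end))
    stop("length_at: t outside the trace domain [0, ", t_end, "]")
  idx <- findInterval(t, trace$event_times)
  trace$lengths[pmax(idx, 1L)]
}

#' Instantaneous force on a filament
#'
#' Force applied at time `t` under a protocol: 0, `f_const`, or
#' `kappa * L(t)` (piecewise constant between events).
#'
#' @inheritParams length_at
#' @param protocol a [force_protocol()] object.
#' @return Force(s), pN.
#' @export
force_at <- function(trace, t, protocol) {
  check_domain(trace, t)
  switch(protocol$mode,
         zero = rep(0, length(t)),
         constant = rep(protocol$f_const, length(t)),
         length_proportional = protocol$kappa * length_at(trace, t))
}

check_domain <- function(trace, t) {
  t_end <- if (is.na(trace$dissociation_time)) trace$horizon
           else trace$dissociation_time
  if (any(t < 0 | t > t_end))
    stop("force_at: t outside the trace domain [0, ", t_end, "]")
  0
}

#' Serialize trace collections to tabular text
#'
#' Writes one row per recorded event (`filament_id, t_event, length_um,
#' force_pN, event_type`) and, beside it, a per-filament summary file
#' (suffix `_summary.csv`).
#'
#' @param pop a recorded [simulate_population()] result.
#' @param path CSV path for the event table.
#' @return `path`, invisibly.
#' @export
write_traces <- function(pop, path) {
  stopifnot(inherits(pop, "filament_population"))
  protocol <- attr(pop, "protocol")
  rows <- lapply(seq_along(pop), function(i) {
    tr <- pop[[i]]
    if (is.null(tr$event_times)) stop("write_traces: population not recorded")
    n <- length(tr$event_times)
    type <- c("start", rep("addition", max(n - 1L, 0L)))
    if (tr$dissociation_route != "censored" && n > 1L)
      type[n] <- paste0("dissociation_", tr$dissociation_route)
    f <- switch(protocol$mode, zero = rep(0, n),
                constant = rep(protocol$f_const, n),
                length_proportional = protocol$kappa * tr$lengths)
    data.frame(filament_id = i, t_event = tr$event_times,
               length_um = tr$lengths, force_pN = f, event_type = type)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  spath <- sub("\\.csv$", "_summary.csv", path)
  utils::write.csv(population_summary(pop), spath, row.names = FALSE)
  invisible(path)
}
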