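# End-to-end studies: force-ramp parameter recovery, force-regime
# discrimination, mean-length sweeps, CI calibration, plus config I/O and a
# command-line entry point.

#' Default force-ramp experimental design
#'
#' The three flow-rate conditions of the reference anchored-formin pulling
#' assay: drag coefficients 0.051, 0.204 and 0.501 pN/um with initial
#' filament lengths 4.9, 3.2 and 2.6 um and populations of 46, 49 and 49
#' filaments.
#'
#' @return Data frame with columns `kappa`, `L0`, `n`.
#' @export
ramp_designs <- function() {
  data.frame(kappa = c(0.051, 0.204, 0.501),
             L0 = c(4.9, 3.2, 2.6),
             n = c(46L, 49L, 49L))
}

# truth with a single pure Bell route: open route only, always-open FH2
pure_bell_params <- function(k0 = 0.003, delta = 2.7, k_on = 22) {
  formin_params(k_on = k_on, K_co = 1e-9, k_offO0 = k0, delta_O = delta,
                k_offT0 = 0, delta_T = 0)
}

#' Force-ramp parameter recovery study
#'
#' Generates anchored-formin populations under the three-flow-rate pulling
#' design with a known force-dependent truth, runs the full estimation
#' chain — survival fractions, local hazard fits, time-to-force mapping,
#' force binning, detachment-rate correction — and compares the recovered
#' k_off(f) with the generating model. A force bin "matches" when its error
#' rectangle (mean force +/- SD horizontally, corrected bounds
#' `[functional_fraction * k_obs, k_obs]` vertically) intersects the true
#' k_off(f) curve. A log-linear fit of the binned rates against force
#' recovers the zero-force rate and the effective working distance.
#'
#' @param params generating model; default a single-route Bell truth with
#'   zero-force rate 0.003/s and working distance 2.7 nm.
#' @param conds solution conditions (set the elongation speed).
#' @param designs data frame with columns `kappa` (pN/um), `L0` (um), `n`;
#'   default [ramp_designs()].
#' @param movie_duration,frame_interval observation scheme, s.
#' @param functional_fraction fraction of functional anchored formins; the
#'   generator plants matching spurious detachments and the analysis applies
#'   the corresponding correction.
#' @param window local-hazard window (events).
#' @param n_bins force bins (equal-count).
#' @param n_replicates independent experiments simulated per flow condition;
#'   hazard points are pooled across replicates before binning (force-rate
#'   points in the reference assay are likewise averages of 2-3 independent
#'   experiments).
#' @param seed integer seed.
#' @return List: `bins` (hazard points with corrected bounds and truth),
#'   `fraction_bins_within`, `k0_hat`, `delta_hat_nm`, `k0_true`,
#'   `delta_true_nm`, `k0_rel_error`, `delta_rel_error`, `n_total`, `seed`.
#' @export
run_recovery <- function(params = pure_bell_params(),
                         conds = conditions(actin = 1),
                         designs = ramp_designs(),
                         movie_duration = 1200, frame_interval = 5,
                         functional_fraction = 0.74,
                         window = 10, n_bins = 8, n_replicates = 3,
                         seed = 1L) {
  v_um_s <- elongation_rate(conds, 0, params) * SUBUNIT_NM / 1000
  grid <- expand.grid(cond = seq_len(nrow(designs)),
                      rep = seq_len(n_replicates))
  set.seed(seed)
  exp_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  pts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    i <- grid$cond[g]
    des <- experiment_design(
      "formin_anchored", frame_interval = frame_interval,
      movie_duration = movie_duration, n_filaments = designs$n[i],
      conds = conds,
      protocol = force_protocol("length_proportional",
                                kappa = designs$kappa[i],
                                L0 = designs$L0[i]),
      functional_fraction = functional_fraction)
    tab <- generate_experiment(des, params, seed = exp_seeds[g])
    curve <- survival_from_events(tab)
    hz <- local_hazard(curve, window = window)
    data.frame(f = map_time_to_force(hz$t, designs$kappa[i], designs$L0[i],
                                     v_um_s),
               k = hz$hazard)
  }))
  pts <- pts[pts$k > 0, ]
  bins <- bin_by_force(pts$f, pts$k, n_bins = n_bins)
  bounds <- correct_detachment_rate(bins$k_obs, functional_fraction)
  bins$k_off_low <- bounds$k_off_low
  bins$k_off_high <- bounds$k_off_high
  k_true_at <- function(f) dissociation_rate(conds, f, params)$k_off
  bins$k_true <- vapply(bins$f, k_true_at, 0)
  # truth is monotone in f: the error rectangle intersects the curve iff
  bins$within <- k_true_at(pmax(bins$f - bins$f_sd, 0)) <= bins$k_off_high &
    k_true_at(bins$f + bins$f_sd) >= bins$k_off_low
  if (nrow(bins) < 3)
    stop("run_recovery: fewer than 3 force bins; fit under-determined")
  fit <- stats::lm(log(k_obs) ~ f, data = bins)
  delta_hat <- unname(stats::coef(fit)[2L]) * conds$kBT
  k0_hat <- exp(unname(stats::coef(fit)[1L]))
  f_lo <- min(bins$f); f_hi <- max(bins$f)
  delta_true <- log(k_true_at(f_hi) / k_true_at(f_lo)) / (f_hi - f_lo) *
    conds$kBT
  k0_true <- k_true_at(0)
  list(bins = bins,
       fraction_bins_within = mean(bins$within),
       k0_hat = k0_hat, delta_hat_nm = delta_hat,
       k0_true = k0_true, delta_true_nm = delta_true,
       k0_rel_error = abs(k0_hat - k0_true) / k0_true,
       delta_rel_error = if (delta_true > 0)
         abs(delta_hat - delta_true) / delta_true else NA_real_,
       n_total = sum(designs$n), seed = seed)
}

#' Force-regime discrimination study
#'
#' Builds the two limiting parameterizations of the two-route model — the
#' open route carrying the working distance (`delta_O = delta, delta_T = 0`)
#' versus the transition route carrying it (`delta_O = 0, delta_T = delta`)
#' — evaluates k_off(f) families across actin concentrations, and classifies
#' each with [koff_force_family()]. In the first regime the actin-dependent
#' curves converge under force (the actin-independent open route takes
#' over); in the second they stay separated. Both regimes keep the
#' actin-dependent transition route dominant at zero force.
#'
#' @param actin_list actin concentrations, uM (>= 2 values).
#' @param f_grid increasing force grid, pN.
#' @param delta working distance assigned to the dominant route, nm.
#' @param params_base base parameter set to modify.
#' @return List with `family_open_route` (converging scenario),
#'   `family_transition_route` (separated scenario), logical checks
#'   `converging_ok`, `separated_ok`, `actin_dependent_at_zero`.
#' @export
run_regimes <- function(actin_list = c(0.3, 1, 2),
                        f_grid = seq(0, 6, by = 0.2), delta = 2.7,
                        params_base = formin_params()) {
  if (length(actin_list) < 2)
    stop("run_regimes: need >= 2 actin concentrations")
  pB <- pC <- params_base
  pB$delta_O <- delta; pB$delta_T <- 0
  pC$delta_O <- 0;     pC$delta_T <- delta
  cn <- conditions(actin = 1)
  famB <- koff_force_family(actin_list, f_grid, cn, pB)
  famC <- koff_force_family(actin_list, f_grid, cn, pC)
  k0B <- famB$curves$k_off[famB$curves$f == 0]
  k0C <- famC$curves$k_off[famC$curves$f == 0]
  list(family_open_route = famB, family_transition_route = famC,
       converging_ok = famB$regime == "converging",
       separated_ok = famC$regime == "separated",
       actin_dependent_at_zero = !is.unsorted(k0B, strictly = TRUE) &&
         !is.unsorted(k0C, strictly = TRUE))
}

#' Mean filament length study
#'
#' Closed-form sweeps of the mean filament length (elongation rate over
#' dissociation rate): versus actin (normalized at 1 uM), versus profilin
#' (normalized at 0 profilin), and versus force (normalized at f = 0).
#'
#' @param params a [formin_params()] object.
#' @param actin_grid,profilin_grid,force_grid sweep grids (uM, uM, pN); the
#'   normalization points 1 uM, 0 uM and 0 pN are added if absent.
#' @param conds_base conditions supplying kBT and KCl.
#' @return List of data frames `vs_actin`, `vs_profilin`, `vs_force`, each
#'   with the sweep variable, `L_um` and `L_norm`.
#' @export
run_mean_length <- function(params = formin_params(),
                            actin_grid = c(0.3, 0.5, 1, 2, 4),
                            profilin_grid = c(0, 0.5, 1, 2, 5, 10, 20),
                            force_grid = seq(0, 6, by = 0.5),
                            conds_base = conditions()) {
  actin_grid <- sort(unique(c(1, actin_grid)))
  profilin_grid <- sort(unique(c(0, profilin_grid)))
  force_grid <- sort(unique(c(0, force_grid)))
  len_at <- function(actin, profilin, f) {
    cn <- conds_base
    cn$actin <- actin; cn$profilin <- profilin
    mean_filament_length(cn, f, params)
  }
  la <- vapply(actin_grid, len_at, 0, profilin = 0, f = 0)
  lp <- vapply(profilin_grid, function(p) len_at(1, p, 0), 0)
  lf <- vapply(force_grid, function(f) len_at(1, 0, f), 0)
  list(vs_actin = data.frame(actin_uM = actin_grid, L_um = la,
                             L_norm = la / la[actin_grid == 1]),
       vs_profilin = data.frame(profilin_uM = profilin_grid, L_um = lp,
                                L_norm = lp / lp[profilin_grid == 0]),
       vs_force = data.frame(force_pN = force_grid, L_um = lf,
                             L_norm = lf / lf[force_grid == 0]))
}

#' Parameter/config file I/O
#'
#' Reads a structured text config (YAML or JSON, by extension) with a
#' `constructs` block (named [formin_params()] field lists) and an optional
#' `conditions` block (named [conditions()] field lists).
#'
#' @param path config file path (.yaml/.yml or .json).
#' @return List with `params` (named list of `formin_params`) and `conds`
#'   (named list of `conditions`).
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("read_params_config: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("read_params_config: unsupported extension '", ext, "'")
  if (is.null(raw$constructs))
    stop("read_params_config: config has no 'constructs' block")
  params <- lapply(raw$constructs, function(p) do.call(formin_params, p))
  conds <- if (!is.null(raw$conditions))
    lapply(raw$conditions, function(cn) do.call(conditions, cn))
  else list()
  list(params = params, conds = conds)
}

#' CI calibration study with report
#'
#' Runs [ci_calibration()] and writes a one-row coverage report CSV when an
#' output directory is given.
#'
#' @inheritParams ci_calibration
#' @param out_dir optional output directory.
#' @return The [ci_calibration()] object, invisibly when writing.
#' @export
run_ci_calibration <- function(n = 35, k0 = 0.01, m = 10000, seed = 1L,
                               out_dir = NULL) {
  cal <- ci_calibration(n, k0, m, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(n = cal$n, k0 = cal$k0, m = cal$m, seed = cal$seed,
                 coverage = cal$coverage, half_width_65 = cal$half_width_65,
                 k0_over_sqrt_n = cal$k0 / sqrt(cal$n)),
      file.path(out_dir, "ci_calibration.csv"), row.names = FALSE)
    write_manifest(out_dir, "calibrate-ci", seed,
                   list(n = n, k0 = k0, m = m))
    invisible(cal)
  } else cal
}

write_manifest <- function(out_dir, subcommand, seed, args,
                           config_path = NULL) {
  man <- list(package = "forminproc",
              version = as.character(utils::packageVersion("forminproc")),
              subcommand = subcommand, seed = seed, args = args)
  if (!is.null(config_path))
    man$config_md5 <- unname(tools::md5sum(config_path))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

cli_usage <- function() {
  paste(
    "usage: forminproc <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate      simulate a filament population (CSV traces)",
    "  analyze       fit a survival curve from an event table CSV",
    "  recover       force-ramp parameter recovery study",
    "  regimes       force-regime discrimination study",
    "  mean-length   mean filament length sweeps",
    "  calibrate-ci  Monte-Carlo CI calibration",
    "",
    "common options: --seed INT --out DIR [--config FILE]",
    sep = "\n")
}

cli_opt <- function(args, name, default = NULL, flag = FALSE) {
  i <- which(args == paste0("--", name))
  if (!length(i)) return(default)
  if (flag) return(TRUE)
  if (i[1L] + 1L > length(args))
    stop("cli: option --", name, " needs a value", call. = FALSE)
  args[i[1L] + 1L]
}

#' Command-line entry point
#'
#' Dispatches the study subcommands (`simulate`, `analyze`, `recover`,
#' `regimes`, `mean-length`, `calibrate-ci`) from an argument vector, writing
#' CSV outputs and a `manifest.json` (package version, seed, arguments,
#' config checksum) into the output directory. Intended to back a thin
#' Rscript wrapper (see `inst/cli/forminproc.R`).
#'
#' @param argv character vector of command-line arguments.
#' @return Integer exit status: 0 on success, 2 on usage errors, 1 on
#'   runtime failure.
#' @export
cli <- function(argv = character()) {
  if (!length(argv)) { message(cli_usage()); return(2L) }
  sub <- argv[1L]; rest <- argv[-1L]
  known <- c("simulate", "analyze", "recover", "regimes", "mean-length",
             "calibrate-ci")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n\n", cli_usage())
    return(2L)
  }
  out_dir <- cli_opt(rest, "out", "forminproc_out")
  seed <- as.integer(cli_opt(rest, "seed", "1"))
  status <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    config <- cli_opt(rest, "config")
    params <- if (!is.null(config)) read_params_config(config)$params[[1L]]
              else formin_params()
    switch(sub,
      simulate = {
        n <- as.integer(cli_opt(rest, "n", "40"))
        horizon <- as.numeric(cli_opt(rest, "horizon", "1500"))
        mode <- cli_opt(rest, "mode", "zero")
        prot <- force_protocol(mode,
                               f_const = as.numeric(cli_opt(rest, "f", "0")),
                               kappa = as.numeric(cli_opt(rest, "kappa", "0.2")),
                               L0 = as.numeric(cli_opt(rest, "L0", "3")))
        actin <- as.numeric(cli_opt(rest, "actin", "1"))
        profilin <- as.numeric(cli_opt(rest, "profilin", "0"))
        pop <- simulate_population(n, params,
                                   conditions(actin = actin,
                                              profilin = profilin),
                                   prot, horizon, seed = seed)
        write_traces(pop, file.path(out_dir, "traces.csv"))
        write_manifest(out_dir, sub, seed,
                       list(n = n, horizon = horizon, mode = mode,
                            actin = actin, profilin = profilin), config)
      },
      analyze = {
        events <- cli_opt(rest, "events")
        if (is.null(events)) stop("analyze: --events FILE is required")
        tab <- read_event_table(events)
        est <- fit_exponential(survival_from_events(tab))
        utils::write.csv(
          data.frame(k = est$k, ci65_low = est$ci65_low,
                     ci65_high = est$ci65_high, n = est$n,
                     method = est$method),
          file.path(out_dir, "rate_estimate.csv"), row.names = FALSE)
        write_manifest(out_dir, sub, seed, list(events = events), config)
      },
      recover = {
        rec <- run_recovery(seed = seed)
        utils::write.csv(rec$bins, file.path(out_dir, "recovery_bins.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(k0_hat = rec$k0_hat, delta_hat_nm = rec$delta_hat_nm,
                     k0_true = rec$k0_true,
                     delta_true_nm = rec$delta_true_nm,
                     fraction_bins_within = rec$fraction_bins_within),
          file.path(out_dir, "recovery_summary.csv"), row.names = FALSE)
        write_manifest(out_dir, sub, seed, list(), config)
      },
      regimes = {
        reg <- run_regimes(params_base = params)
        utils::write.csv(reg$family_open_route$curves,
                         file.path(out_dir, "regime_open_route.csv"),
                         row.names = FALSE)
        utils::write.csv(reg$family_transition_route$curves,
                         file.path(out_dir, "regime_transition_route.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(converging_ok = reg$converging_ok,
                     separated_ok = reg$separated_ok,
                     actin_dependent_at_zero = reg$actin_dependent_at_zero),
          file.path(out_dir, "regime_summary.csv"), row.names = FALSE)
        write_manifest(out_dir, sub, seed, list(), config)
      },
      `mean-length` = {
        ml <- run_mean_length(params = params)
        utils::write.csv(ml$vs_actin, file.path(out_dir, "length_vs_actin.csv"),
                         row.names = FALSE)
        utils::write.csv(ml$vs_profilin,
                         file.path(out_dir, "length_vs_profilin.csv"),
                         row.names = FALSE)
        utils::write.csv(ml$vs_force, file.path(out_dir, "length_vs_force.csv"),
                         row.names = FALSE)
        write_manifest(out_dir, sub, seed, list(), config)
      },
      `calibrate-ci` = {
        run_ci_calibration(n = as.integer(cli_opt(rest, "n", "35")),
                           k0 = as.numeric(cli_opt(rest, "k0", "0.01")),
                           m = as.integer(cli_opt(rest, "m", "10000")),
                           seed = seed, out_dir = out_dir)
      })
    0L
  }, error = function(e) {
    message("forminproc ", sub, ": ", conditionMessage(e))
    1L
  })
  status
}
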