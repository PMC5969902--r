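# Experiment-shaped synthetic datasets: frame-interval sampling, censoring
# at movie end, striped-filament alternation schedules, and anchored-formin
# detachment with a functional-fraction bound.

#' Design of a simulated single-filament experiment
#'
#' Describes one microfluidics-style observation scheme:
#' \describe{
#'   \item{seed_anchored}{filaments grow from anchored seeds with a formin at
#'     the free barbed end; dissociation observed at fixed frame intervals,
#'     essentially force-free.}
#'   \item{striped}{unanchored formins at zero force; solution conditions
#'     alternate on a fixed schedule (e.g. 100 s unlabeled / 20 s labeled),
#'     and the filament is imaged once per cycle, so measured rates are
#'     duration-weighted composites of the per-condition rates.}
#'   \item{formin_anchored}{formins anchored to the surface; filament
#'     detachment reveals dissociation, and the flow applies a force
#'     proportional to filament length. A fraction of apparent detachments
#'     is spurious (non-functional anchoring), bounded by
#'     `functional_fraction`.}
#' }
#'
#' @param configuration one of `"seed_anchored"`, `"striped"`,
#'   `"formin_anchored"`.
#' @param frame_interval acquisition interval, s (dissociation times are
#'   rounded up to the next frame).
#' @param movie_duration total observation time, s; filaments surviving past
#'   the last frame are censored.
#' @param n_filaments population size.
#' @param conds a [conditions()] object (ignored in striped mode, where the
#'   schedule supplies conditions).
#' @param conditions_schedule striped mode only: list of
#'   `list(conds = conditions(...), duration = seconds)` entries, cycled for
#'   the whole movie.
#' @param protocol a [force_protocol()] object.
#' @param functional_fraction fraction of anchored formins still present and
#'   functional at the end of the experiment, in (0, 1]; the complement
#'   produces spurious detachments (formin_anchored mode only).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(configuration = c("seed_anchored", "striped",
                                                "formin_anchored"),
                              frame_interval = 5, movie_duration = 1500,
                              n_filaments = 40, conds = conditions(),
                              conditions_schedule = NULL,
                              protocol = force_protocol("zero"),
                              functional_fraction = 1) {
  configuration <- match.arg(configuration)
  if (frame_interval <= 0) stop("experiment_design: frame_interval must be > 0")
  if (movie_duration <= 0) stop("experiment_design: movie_duration must be > 0")
  if (n_filaments < 1) stop("experiment_design: n_filaments must be >= 1")
  if (functional_fraction <= 0 || functional_fraction > 1)
    stop("experiment_design: functional_fraction must be in (0, 1]")
  if (configuration == "striped") {
    if (is.null(conditions_schedule) || length(conditions_schedule) < 1L)
      stop("experiment_design: striped mode needs a conditions_schedule")
    durs <- vapply(conditions_schedule, function(s) s$duration, 0)
    if (any(durs <= 0)) stop("experiment_design: schedule durations must be > 0")
    if (sum(durs) < frame_interval)
      stop("experiment_design: schedule cycle shorter than frame_interval")
  }
  structure(list(configuration = configuration,
                 frame_interval = frame_interval,
                 movie_duration = movie_duration,
                 n_filaments = as.integer(n_filaments), conds = conds,
                 conditions_schedule = conditions_schedule,
                 protocol = protocol,
                 functional_fraction = functional_fraction),
            class = "experiment_design")
}

# One filament through a cyclic conditions schedule (zero/constant force).
sim_striped_filament <- function(params, schedule, protocol, horizon, L0) {
  t <- 0; L <- L0; i <- 1L
  repeat {
    seg <- schedule[[i]]
    seg_end <- min(t + seg$duration, horizon)
    res <- run_core(params, seg$conds, protocol, t, L, seg_end,
                    record = FALSE, transition_mode = "instant")
    t <- res$t_end; L <- res$L_end
    if (res$dissociated)
      return(list(time = t, route = c("open", "transition")[res$route],
                  length = L))
    if (t >= horizon) return(list(time = NA_real_, route = "censored",
                                  length = L))
    i <- if (i == length(schedule)) 1L else i + 1L
  }
}

#' Generate a synthetic single-filament event table
#'
#' Simulates every filament of an [experiment_design()] with the exact
#' event-driven simulator, then imposes the observation process: dissociation
#' times are rounded up to the next acquisition frame, filaments surviving
#' past the last frame are censored, and in `formin_anchored` mode a
#' `(1 - functional_fraction)` subset of filaments detaches spuriously at a
#' uniform time. True (hidden) times and routes are carried alongside for
#' validation and are segregated on write (see [write_event_table()]).
#'
#' @param design an [experiment_design()] object.
#' @param params a [formin_params()] object.
#' @param seed integer seed.
#' @return A data frame of class `event_table`, one row per filament:
#'   observed columns `filament_id`, `observed_time`, `censored`,
#'   `initial_length_um`, `configuration`, `actin_uM`, `profilin_uM`,
#'   `kcl_mM`, `frame_interval`; hidden truth columns `true_time`,
#'   `true_route`.
#' @export
generate_experiment <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  validate_formin_params(params)
  set.seed(seed)
  n <- design$n_filaments
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  protocol <- design$protocol
  L0s <- if (protocol$mode == "length_proportional" && protocol$L0_cv > 0) {
    sdlog <- sqrt(log(1 + protocol$L0_cv^2))
    stats::rlnorm(n, meanlog = log(protocol$L0) - sdlog^2 / 2, sdlog = sdlog)
  } else rep(protocol$L0, n)
  spurious_frac <- 1 - design$functional_fraction
  fragile <- if (design$configuration == "formin_anchored" &&
                 spurious_frac > 0) {
    stats::runif(n) < spurious_frac
  } else rep(FALSE, n)
  spurious_times <- stats::runif(n, 0, design$movie_duration)

  rows <- lapply(seq_len(n), function(i) {
    set.seed(child_seeds[i])
    if (design$configuration == "striped") {
      s <- sim_striped_filament(params, design$conditions_schedule, protocol,
                                design$movie_duration, L0s[i])
      true_time <- s$time; route <- s$route
    } else {
      res <- run_core(params, design$conds, protocol, 0, L0s[i],
                      design$movie_duration, record = FALSE,
                      transition_mode = "instant")
      true_time <- if (res$dissociated) res$t_end else NA_real_
      route <- c("censored", "open", "transition")[res$route + 1L]
    }
    if (fragile[i] &&
        (is.na(true_time) || spurious_times[i] < true_time)) {
      true_time <- spurious_times[i]
      route <- "spurious"
    }
    data.frame(filament_id = i, true_time = true_time, true_route = route,
               initial_length_um = L0s[i])
  })
  tab <- do.call(rbind, rows)

  fi <- design$frame_interval
  last_frame <- floor(design$movie_duration / fi) * fi
  obs_frame <- ceiling(tab$true_time / fi) * fi
  observed <- !is.na(tab$true_time) & obs_frame <= last_frame
  cond1 <- if (design$configuration == "striped")
    design$conditions_schedule[[1L]]$conds else design$conds
  out <- data.frame(
    filament_id = tab$filament_id,
    observed_time = ifelse(observed, obs_frame, last_frame),
    censored = !observed,
    initial_length_um = tab$initial_length_um,
    configuration = design$configuration,
    actin_uM = cond1$actin, profilin_uM = cond1$profilin,
    kcl_mM = cond1$kcl, frame_interval = fi,
    true_time = tab$true_time, true_route = tab$true_route)
  class(out) <- c("event_table", "data.frame")
  attr(out, "design") <- design
  out
}

event_table_observed_cols <- c("filament_id", "observed_time", "censored",
                               "initial_length_um", "configuration",
                               "actin_uM", "profilin_uM", "kcl_mM",
                               "frame_interval")
event_table_truth_cols <- c("filament_id", "true_time", "true_route")

truth_path <- function(path) sub("(\\.[^.]*)?$", "_truth\\1", path)

#' Write an event table (truth segregated)
#'
#' Writes the observed columns to `path` and the hidden truth columns
#' (`true_time`, `true_route`) to a sibling file with suffix `_truth`, so
#' analysis stages reading `path` cannot accidentally consume the ground
#' truth.
#'
#' @param table an `event_table` from [generate_experiment()].
#' @param path CSV path for the observed table.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  utils::write.csv(table[, event_table_observed_cols], path,
                   row.names = FALSE)
  utils::write.csv(table[, event_table_truth_cols], truth_path(path),
                   row.names = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path CSV written by [write_event_table()].
#' @param with_truth also read the sibling `_truth` file and join the hidden
#'   columns back (validation only).
#' @return An `event_table` data frame.
#' @export
read_event_table <- function(path, with_truth = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(event_table_observed_cols, names(tab))
  if (length(missing))
    stop("read_event_table: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (with_truth) {
    tp <- truth_path(path)
    if (!file.exists(tp)) stop("read_event_table: no truth file at ", tp)
    tr <- utils::read.csv(tp, stringsAsFactors = FALSE)
    missing_t <- setdiff(event_table_truth_cols, names(tr))
    if (length(missing_t))
      stop("read_event_table: truth file missing column(s): ",
           paste(missing_t, collapse = ", "))
    tab <- merge(tab, tr, by = "filament_id", sort = FALSE)
  }
  class(tab) <- c("event_table", "data.frame")
  tab
}
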