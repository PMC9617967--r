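#' Full simulation configuration
#'
#' Bundles the three dimer species, lattice geometry, rate law and run
#' settings for one stochastic growth simulation.
#'
#' @param species List of three [dimer_species()] in id order (Tubb3, Tubb4,
#'   other Tubbs); typically from [make_species()].
#' @param lattice A [lattice_config()].
#' @param rates A [rate_constants()].
#' @param penalty A [penalty_rule()].
#' @param n_events Number of executed events per run (default 5000).
#' @param rate_floor Dissociation events with rate below this (s^-1) are
#'   skipped when enumerating candidates (default 1e-12).  Deeply buried
#'   dimers have astronomically small cascade rates; skipping them bounds
#'   the per-step cost while perturbing the total propensity by a relative
#'   amount far below 1e-9.
#' @param start_composition `"proportional"` (start-column dimers sampled
#'   with probabilities proportional to species concentrations, the default)
#'   or `"uniform"` (equal probability across the three types).
#' @param on_rate_scope `"per_protofilament"` (default): each protofilament
#'   tip binds each species at k_on * C / penalty.  `"per_microtubule"`:
#'   the total binding propensity k_on * C is split evenly across the
#'   protofilaments (calibration alternative).
#' @param stack_longitudinal_bonds Also break longitudinal bonds internal to
#'   a departing stack (default FALSE; see [stack_off_rate()]).
#' @param subtract_start_length Measure growth net of the seeded start
#'   length when computing velocity (default TRUE).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species = make_species(),
                              lattice = lattice_config(),
                              rates = rate_constants(),
                              penalty = penalty_rule(),
                              n_events = 5000,
                              rate_floor = 1e-12,
                              start_composition = c("proportional", "uniform"),
                              on_rate_scope = c("per_protofilament",
                                                "per_microtubule"),
                              stack_longitudinal_bonds = FALSE,
                              subtract_start_length = TRUE) {
  stopifnot(inherits(lattice, "lattice_config"),
            inherits(rates, "rate_constants"),
            inherits(penalty, "penalty_rule"),
            n_events >= 1, rate_floor >= 0)
  sv <- species_vectors(species)  # validates the species list
  if (all(sv$conc == 0) && identical(start_composition[1], "proportional")) {
    start_composition <- "uniform"  # proportional sampling is undefined
  }
  structure(
    list(species = species, lattice = lattice, rates = rates,
         penalty = penalty, n_events = as.integer(n_events),
         rate_floor = as.numeric(rate_floor),
         start_composition = match.arg(start_composition),
         on_rate_scope = match.arg(on_rate_scope),
         stack_longitudinal_bonds = isTRUE(stack_longitudinal_bonds),
         subtract_start_length = isTRUE(subtract_start_length)),
    class = "simulation_config")
}

#' Growth velocity from run outputs
#'
#' velocity = mean protofilament length gained / total elapsed time,
#' converted to um/s via the dimer length.  With the (default) baseline
#' convention, "length gained" is net of the seeded start length, so a
#' no-growth run has velocity 0.
#'
#' @param mean_added_dimers Mean over protofilaments of dimers added net of
#'   the baseline (may be negative on net shrinkage).
#' @param total_time Total elapsed simulated time, s (> 0).
#' @param lattice A [lattice_config()] providing the dimer length.
#' @return Velocity in um/s.
#' @export
growth_velocity <- function(mean_added_dimers, total_time,
                            lattice = lattice_config()) {
  stopifnot(inherits(lattice, "lattice_config"))
  if (!is.finite(total_time) || total_time <= 0) {
    stop("total_time must be > 0", call. = FALSE)
  }
  mean_added_dimers * lattice$dimer_length / 1000 / total_time
}

#' Run one growth simulation
#'
#' Executes `n_events` first-reaction kinetic Monte Carlo steps: every
#' candidate event (3 binding channels per protofilament tip plus one
#' cascade-dissociation channel per occupied dimer) receives an exponential
#' waiting time t = -ln(U)/rate from a fresh uniform draw, and the minimum-
#' time event executes.  All randomness flows through R's generator, so a
#' given `seed` reproduces the run exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for the run.
#' @return An object of class `simulation_result`: fields `total_time` (s),
#'   `lengths` (dimers per protofilament), `added_per_pf` (net of start
#'   length), `composition_counts` and `added_counts` (per species),
#'   `velocity` (um/s), `n_binding_events`, `n_dissociation_events`,
#'   `steps_done`, `truncated` (TRUE if the run hit an absorbed state before
#'   `n_events`), `columns` (final lattice) and `seed`.
#' @examples
#' cfg <- simulation_config(n_events = 200)
#' run_simulation(cfg, seed = 1)
#' @export
run_simulation <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  sv <- species_vectors(config$species)
  set.seed(as.integer(seed))
  raw <- .kmc_run_cpp(
    sv$dg_long, sv$dg_lat, sv$conc, config$rates$k_on,
    config$penalty$divisors, config$lattice$n_protofilaments,
    config$lattice$start_length, config$n_events, config$rate_floor,
    identical(config$start_composition, "uniform"),
    identical(config$on_rate_scope, "per_microtubule"),
    config$stack_longitudinal_bonds)
  finalize_result(raw, config, seed)
}

finalize_result <- function(raw, config, seed) {
  start <- config$lattice$start_length
  added <- raw$lengths - start
  baseline <- if (config$subtract_start_length) mean(added)
              else mean(raw$lengths)
  vel <- if (raw$total_time > 0) {
    growth_velocity(baseline, raw$total_time, config$lattice)
  } else NA_real_
  structure(
    list(total_time = raw$total_time, lengths = raw$lengths,
         added_per_pf = added, composition_counts = raw$composition_counts,
         added_counts = raw$added_counts, velocity = vel,
         n_binding_events = raw$n_binding_events,
         n_dissociation_events = raw$n_dissociation_events,
         n_dimers_removed = raw$n_dimers_removed,
         steps_done = raw$steps_done, truncated = raw$truncated,
         columns = raw$columns, seed = as.integer(seed)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d events in %.3f s, velocity %.4f um/s%s\n",
    x$steps_done, x$total_time, x$velocity,
    if (x$truncated) " (truncated: absorbed state)" else ""))
  invisible(x)
}

#' Species composition of the final lattice
#'
#' Counts of each dimer species present in the final lattice, normalised by
#' the total dimer count.
#'
#' @param result A `simulation_result`.
#' @return Named numeric vector (tubb3, tubb4, other) summing to 1.
#' @export
composition_fractions <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  tot <- sum(result$composition_counts)
  if (tot == 0) stop("final lattice is empty", call. = FALSE)
  stats::setNames(result$composition_counts / tot,
                  c("tubb3", "tubb4", "other"))
}

#' Derive per-replicate child seeds from a master seed
#'
#' Child seeds are drawn once from the master-seeded stream, so replicate k
#' always receives the same seed regardless of evaluation order or
#' partitioning.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' Replicate simulations and summary statistics
#'
#' Runs `n_replicates` independent simulations with documented child seeds
#' and reports the velocity sample with its mean and standard error
#' (SEM = sd / sqrt(n)).
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of runs (SEM is reported for n >= 2).
#' @param seed Master seed; expanded via [derive_seeds()].
#' @return List with `velocities`, `mean`, `sem`, `n`, `seeds`, and
#'   `results` (the individual `simulation_result`s) unless
#'   `keep_results = FALSE`.
#' @param keep_results Keep the per-run result objects (default FALSE).
#' @export
replicate_stats <- function(config, n_replicates, seed,
                            keep_results = FALSE) {
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(seed, n_replicates)
  results <- lapply(seeds, function(s) run_simulation(config, s))
  v <- vapply(results, function(r) r$velocity, numeric(1))
  out <- list(velocities = v, mean = mean(v),
              sem = if (n_replicates > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
              n = n_replicates, seeds = seeds)
  if (keep_results) out$results <- results
  out
}
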