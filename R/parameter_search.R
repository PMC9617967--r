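#' Velocity acceptance window
#'
#' @param center Window center, um/s.
#' @param half_width Half-width, um/s (> 0).
#' @return An object of class `velocity_window`.
#' @export
velocity_window <- function(center, half_width) {
  stopifnot(is.finite(center), half_width > 0)
  structure(list(center = as.numeric(center),
                 half_width = as.numeric(half_width)),
            class = "velocity_window")
}

in_window <- function(v, w) {
  v >= w$center - w$half_width & v <= w$center + w$half_width
}

#' Energy-parameter scan grid
#'
#' The calibration grid for the Tubb3 and Tubb4 bond energies: longitudinal
#' energies from -3 to -9 RT in 0.5 RT steps, lateral energies from -1 RT
#' down to the respective longitudinal value (lateral bonds must stay weaker
#' than longitudinal ones for a stable lattice), full Cartesian product over
#' the two isotypes: 143 (long, lat) pairs per isotype, 20449 4-tuples.
#'
#' @param long_range Longitudinal energy range endpoints, RT (default
#'   `c(-3, -9)`).
#' @param lat_start Weakest lateral energy, RT (default -1).
#' @param step Grid step, RT (default 0.5).
#' @return Data frame with columns `dg_long_tubb3`, `dg_lat_tubb3`,
#'   `dg_long_tubb4`, `dg_lat_tubb4`.
#' @export
grid_points <- function(long_range = c(-3, -9), lat_start = -1, step = 0.5) {
  longs <- seq(max(long_range), min(long_range), by = -step)
  pairs <- do.call(rbind, lapply(longs, function(lo) {
    data.frame(long = lo, lat = seq(lat_start, lo, by = -step))
  }))
  g <- expand.grid(i3 = seq_len(nrow(pairs)), i4 = seq_len(nrow(pairs)))
  data.frame(dg_long_tubb3 = pairs$long[g$i3], dg_lat_tubb3 = pairs$lat[g$i3],
             dg_long_tubb4 = pairs$long[g$i4], dg_lat_tubb4 = pairs$lat[g$i4])
}

scan_config <- function(row, concentrations, n_events = 5000) {
  eps <- energy_parameter_set(row$dg_long_tubb3, row$dg_lat_tubb3,
                              row$dg_long_tubb4, row$dg_lat_tubb4)
  simulation_config(make_species(eps, concentrations), n_events = n_events)
}

#' Evaluate a grid of energy parameter sets
#'
#' For each grid row, runs `n_runs` replicate simulations under the control
#' and the knockdown concentrations and records mean velocity and SEM for
#' both.  Each (grid point, condition) pair receives its own child seed
#' derived from `seed`, so results do not depend on evaluation order or
#' partitioning.
#'
#' @param grid Data frame as returned by [grid_points()] (or a subset).
#' @param control,kd The two [isotype_concentrations()] conditions.
#' @param n_runs Replicates per condition per grid point.
#' @param seed Master seed.
#' @param n_events Events per run (default 5000).
#' @return `grid` with appended columns `v_control_mean`, `v_control_sem`,
#'   `v_kd_mean`, `v_kd_sem`, `n_runs`.
#' @export
evaluate_grid <- function(grid, control = control_concentrations(),
                          kd = knockdown_concentrations(), n_runs = 25,
                          seed = 1, n_events = 5000) {
  stopifnot(nrow(grid) >= 1, n_runs >= 1)
  point_seeds <- matrix(derive_seeds(seed, 2L * nrow(grid)), ncol = 2)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    rc <- replicate_stats(scan_config(row, control, n_events), n_runs,
                          point_seeds[i, 1])
    rk <- replicate_stats(scan_config(row, kd, n_events), n_runs,
                          point_seeds[i, 2])
    data.frame(v_control_mean = rc$mean, v_control_sem = rc$sem,
               v_kd_mean = rk$mean, v_kd_sem = rk$sem)
  })
  cbind(grid, do.call(rbind, res), n_runs = n_runs)
}

#' Filter scan results by velocity windows
#'
#' Keeps parameter sets whose mean control velocity lies inside
#' `control_window` and whose mean knockdown velocity lies inside
#' `kd_window` (both conditions must coincide).
#'
#' @param results Output of [evaluate_grid()].
#' @param control_window,kd_window [velocity_window()]s.  Defaults are the
#'   first-pass experimental windows 0.167 +/- 0.006 and 0.201 +/- 0.008
#'   um/s.
#' @return The surviving rows of `results`.
#' @export
filter_by_windows <- function(results,
                              control_window = velocity_window(0.167, 0.006),
                              kd_window = velocity_window(0.201, 0.008)) {
  stopifnot(inherits(control_window, "velocity_window"),
            inherits(kd_window, "velocity_window"))
  keep <- in_window(results$v_control_mean, control_window) &
    in_window(results$v_kd_mean, kd_window)
  results[keep, , drop = FALSE]
}

#' Refine surviving candidates at higher replication
#'
#' Re-evaluates candidate parameter sets with more replicates (default 100
#' per condition) and applies the tighter second-pass windows (0.167 and
#' 0.201 +/- 0.002 um/s).  The returned table mirrors the scan layout
#' (energies plus both velocities).
#'
#' @param candidates Data frame of candidate parameter sets (energy columns
#'   as in [grid_points()]).
#' @param control,kd Concentration conditions.
#' @param n_runs Replicates per condition (default 100).
#' @param control_window,kd_window Second-pass windows.
#' @param seed Master seed.
#' @param n_events Events per run.
#' @return The re-evaluated rows that satisfy both windows.
#' @export
refine <- function(candidates, control = control_concentrations(),
                   kd = knockdown_concentrations(), n_runs = 100,
                   control_window = velocity_window(0.167, 0.002),
                   kd_window = velocity_window(0.201, 0.002),
                   seed = 1, n_events = 5000) {
  stopifnot(nrow(candidates) >= 1)
  energy_cols <- c("dg_long_tubb3", "dg_lat_tubb3",
                   "dg_long_tubb4", "dg_lat_tubb4")
  stopifnot(all(energy_cols %in% names(candidates)))
  rescored <- evaluate_grid(candidates[energy_cols], control, kd,
                            n_runs = n_runs, seed = seed,
                            n_events = n_events)
  filter_by_windows(rescored, control_window, kd_window)
}

#' Velocity landscape over one isotype's energy plane
#'
#' Mean growth velocity on the (dG_long, dG_lat) plane of one isotype with
#' the other isotype's energies held fixed.  Cells violating the stability
#' constraint (lateral energy more negative than longitudinal) are left NA
#' (not computed).  The experimental iso-velocity levels (0.167 and 0.201
#' um/s) are attached as the `"levels"` attribute for contour overlays.
#'
#' @param varying `"tubb3"` or `"tubb4"`: the isotype whose energies vary.
#' @param fixed_energies Length-2 numeric `c(dg_long, dg_lat)` for the fixed
#'   isotype; defaults to the refined values of the non-varying isotype.
#' @param concentrations Condition to simulate under.
#' @param n_runs Replicates per cell.
#' @param seed Master seed.
#' @param n_events Events per run.
#' @param long_range,lat_start,step Grid ranges as in [grid_points()].
#' @return Numeric matrix (rows: longitudinal values, columns: lateral
#'   values, dimnames in RT units) of mean velocities, NA where not
#'   computed.
#' @export
contour_grid <- function(varying = c("tubb3", "tubb4"),
                         fixed_energies = NULL,
                         concentrations = control_concentrations(),
                         n_runs = 25, seed = 1, n_events = 5000,
                         long_range = c(-3, -9), lat_start = -1,
                         step = 0.5) {
  varying <- match.arg(varying)
  if (is.null(fixed_energies)) {
    fixed_energies <- if (varying == "tubb3") c(-7.5, -6) else c(-5, -3)
  }
  stopifnot(length(fixed_energies) == 2)
  longs <- seq(max(long_range), min(long_range), by = -step)
  lats <- seq(lat_start, min(long_range), by = -step)
  m <- matrix(NA_real_, nrow = length(longs), ncol = length(lats),
              dimnames = list(format(longs), format(lats)))
  cell_seeds <- matrix(derive_seeds(seed, length(longs) * length(lats)),
                       nrow = length(longs))
  for (i in seq_along(longs)) {
    for (j in seq_along(lats)) {
      if (lats[j] < longs[i]) next  # unstable: lateral stronger than longitudinal
      e <- if (varying == "tubb3") {
        energy_parameter_set(longs[i], lats[j],
                             fixed_energies[1], fixed_energies[2])
      } else {
        energy_parameter_set(fixed_energies[1], fixed_energies[2],
                             longs[i], lats[j])
      }
      cfg <- simulation_config(make_species(e, concentrations),
                               n_events = n_events)
      m[i, j] <- replicate_stats(cfg, n_runs, cell_seeds[i, j])$mean
    }
  }
  attr(m, "levels") <- c(control = 0.167, tubb3_kd = 0.201)
  m
}
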