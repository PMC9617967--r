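# Configuration files are plain YAML: a handful of scalars plus two small
# blocks (energies, concentrations).  Unknown keys are rejected so typos
# surface immediately instead of silently running defaults.

config_keys <- c("energies", "concentrations", "scenario", "k_on",
                 "n_events", "n_protofilaments", "start_length",
                 "dimer_length", "rate_floor", "penalty",
                 "start_composition", "on_rate_scope",
                 "stack_longitudinal_bonds", "subtract_start_length",
                 "seed", "n_runs")
energy_keys <- c("dg_long_tubb3", "dg_lat_tubb3", "dg_long_tubb4",
                 "dg_lat_tubb4")
conc_keys <- c("c_tubb3", "c_tubb4", "c_other")

#' Load a simulation configuration from a YAML file
#'
#' An empty file yields the full default configuration (k_on = 30, 5000
#' events, 13 protofilaments, start length 10, dimer length 8 nm, refined
#' energies, control concentrations).  Recognised keys: `energies`
#' (`dg_long_tubb3`, `dg_lat_tubb3`, `dg_long_tubb4`, `dg_lat_tubb4`),
#' `concentrations` (`c_tubb3`, `c_tubb4`, `c_other`) or `scenario` (a
#' preset name), `k_on`, `n_events`, `n_protofilaments`, `start_length`,
#' `dimer_length`, `rate_floor`, `penalty` (5 divisors), and the flags
#' `start_composition`, `on_rate_scope`, `stack_longitudinal_bonds`,
#' `subtract_start_length`, plus run settings `seed` and `n_runs`.  Unknown
#' keys are rejected with an error naming the key.
#'
#' @param path Path to the YAML file.
#' @return List with `config` (a [simulation_config()]) and `settings`
#'   (list with `seed`, `n_runs`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$energies)) {
    bad <- setdiff(names(raw$energies), energy_keys)
    if (length(bad)) {
      stop("unknown energies key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  e <- utils::modifyList(unclass(refined_energies()),
                         raw$energies %||% list())
  energies <- energy_parameter_set(e$dg_long_tubb3, e$dg_lat_tubb3,
                                   e$dg_long_tubb4, e$dg_lat_tubb4)
  if (!is.null(raw$concentrations) && !is.null(raw$scenario)) {
    stop("give either `concentrations` or `scenario`, not both",
         call. = FALSE)
  }
  conc <- if (!is.null(raw$scenario)) {
    scenario_concentrations(raw$scenario)
  } else if (!is.null(raw$concentrations)) {
    bad <- setdiff(names(raw$concentrations), conc_keys)
    if (length(bad)) {
      stop("unknown concentrations key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cc <- utils::modifyList(unclass(control_concentrations()),
                            raw$concentrations)
    tryCatch(isotype_concentrations(cc$c_tubb3, cc$c_tubb4, cc$c_other),
             error = function(err) {
               stop("invalid concentrations: ", conditionMessage(err),
                    call. = FALSE)
             })
  } else {
    control_concentrations()
  }
  cfg <- simulation_config(
    species = make_species(energies, conc),
    lattice = lattice_config(
      n_protofilaments = raw$n_protofilaments %||% 13,
      start_length = raw$start_length %||% 10,
      dimer_length = raw$dimer_length %||% 8),
    rates = rate_constants(k_on = raw$k_on %||% 30),
    penalty = penalty_rule(unlist(raw$penalty %||%
                                    c(1, 2, 2, 10, 10))),
    n_events = raw$n_events %||% 5000,
    rate_floor = raw$rate_floor %||% 1e-12,
    start_composition = raw$start_composition %||% "proportional",
    on_rate_scope = raw$on_rate_scope %||% "per_protofilament",
    stack_longitudinal_bonds = raw$stack_longitudinal_bonds %||% FALSE,
    subtract_start_length = raw$subtract_start_length %||% TRUE)
  list(config = cfg,
       settings = list(seed = as.integer(raw$seed %||% 1L),
                       n_runs = as.integer(raw$n_runs %||% 100L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration to a YAML file
#'
#' Writes the configuration so that [load_config()] reproduces it exactly.
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @param seed,n_runs Run settings stored alongside the model parameters.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, seed = 1L, n_runs = 100L) {
  stopifnot(inherits(config, "simulation_config"))
  sv <- species_vectors(config$species)
  out <- list(
    energies = list(dg_long_tubb3 = sv$dg_long[1],
                    dg_lat_tubb3 = sv$dg_lat[1],
                    dg_long_tubb4 = sv$dg_long[2],
                    dg_lat_tubb4 = sv$dg_lat[2]),
    concentrations = list(c_tubb3 = sv$conc[1], c_tubb4 = sv$conc[2],
                          c_other = sv$conc[3]),
    k_on = config$rates$k_on,
    n_events = config$n_events,
    n_protofilaments = config$lattice$n_protofilaments,
    start_length = config$lattice$start_length,
    dimer_length = config$lattice$dimer_length,
    rate_floor = config$rate_floor,
    penalty = config$penalty$divisors,
    start_composition = config$start_composition,
    on_rate_scope = config$on_rate_scope,
    stack_longitudinal_bonds = config$stack_longitudinal_bonds,
    subtract_start_length = config$subtract_start_length,
    seed = as.integer(seed), n_runs = as.integer(n_runs))
  yaml::write_yaml(out, path, precision = 17)  # exact double round-trip
  invisible(path)
}

#' Write a results table
#'
#' Plain TSV (default) or CSV with a header row and full floating-point
#' precision, one row per run or per grid point.
#'
#' @param results Data frame (e.g. replicate table or [evaluate_grid()]
#'   output).
#' @param path Output path, or `""` for stdout.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  utils::write.table(results, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table
#'
#' @param path File written by [write_results()].
#' @param format `"tsv"` or `"csv"`.
#' @return Data frame.
#' @export
read_results <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  utils::read.delim(path, sep = if (format == "tsv") "\t" else ",")
}

#' Run manifest
#'
#' Captures everything needed to reproduce a replicate set bit for bit: the
#' full configuration, the master seed and the derived per-replicate child
#' seeds, the package version and a timestamp.
#'
#' @param config A [simulation_config()].
#' @param master_seed Master seed.
#' @param n_replicates Number of replicates.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, master_seed, n_replicates) {
  sv <- species_vectors(config$species)
  structure(
    list(package_version = as.character(utils::packageVersion("mtkmc")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         master_seed = as.integer(master_seed),
         n_replicates = as.integer(n_replicates),
         child_seeds = derive_seeds(master_seed, n_replicates),
         energies = list(dg_long = sv$dg_long, dg_lat = sv$dg_lat),
         concentrations = sv$conc,
         k_on = config$rates$k_on, n_events = config$n_events,
         n_protofilaments = config$lattice$n_protofilaments,
         start_length = config$lattice$start_length,
         dimer_length = config$lattice$dimer_length,
         rate_floor = config$rate_floor,
         penalty = config$penalty$divisors,
         start_composition = config$start_composition,
         on_rate_scope = config$on_rate_scope,
         stack_longitudinal_bonds = config$stack_longitudinal_bonds,
         subtract_start_length = config$subtract_start_length),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
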