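#' Define a tubulin dimer species
#'
#' A dimer species bundles the bond energetics and the free concentration of
#' one class of alpha/beta-tubulin heterodimer.  Energies are standard free
#' energy changes in RT units (dimensionless multiples of RT) and are
#' expected to be negative for bonds that stabilise the lattice.
#'
#' @param species_id Integer 1, 2 or 3 (type one = Tubb3-containing dimers,
#'   type two = Tubb4, type three = the pooled remaining beta-tubulins).
#' @param label Human-readable label.
#' @param dg_long Longitudinal bond free energy, RT units.  Includes the
#'   immobilisation/conformational terms, so one longitudinal bond is formed
#'   per added dimer.
#' @param dg_lat Lateral bond free energy per full lateral neighbor, RT units.
#' @param concentration Free dimer concentration in uM (never depleted).
#' @return An object of class `dimer_species`.
#' @examples
#' dimer_species(1, "Tubb3", dg_long = -5, dg_lat = -3, concentration = 0.98)
#' @export
dimer_species <- function(species_id, label, dg_long, dg_lat, concentration) {
  stopifnot(length(species_id) == 1L, species_id %in% 1:3)
  if (!is.finite(dg_long) || !is.finite(dg_lat)) {
    stop("bond energies must be finite real numbers", call. = FALSE)
  }
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be a finite value >= 0 uM", call. = FALSE)
  }
  structure(
    list(species_id = as.integer(species_id), label = as.character(label),
         dg_long = as.numeric(dg_long), dg_lat = as.numeric(dg_lat),
         concentration = as.numeric(concentration)),
    class = "dimer_species")
}

#' @export
print.dimer_species <- function(x, ...) {
  cat(sprintf("<dimer_species %d '%s'> dG_long = %g RT, dG_lat = %g RT, C = %g uM\n",
              x$species_id, x$label, x$dg_long, x$dg_lat, x$concentration))
  invisible(x)
}

#' Energy parameter set for the two calibrated isotypes
#'
#' The four free parameters explored by the calibration grid: longitudinal
#' and lateral bond energies of Tubb3- and Tubb4-containing dimers.  The
#' pooled remaining isotypes are held fixed at dG_long = -7 RT and
#' dG_lat = -4 RT.
#'
#' @param dg_long_tubb3,dg_lat_tubb3 Tubb3 bond energies, RT units.
#' @param dg_long_tubb4,dg_lat_tubb4 Tubb4 bond energies, RT units.
#' @return An object of class `energy_parameter_set`.
#' @export
energy_parameter_set <- function(dg_long_tubb3, dg_lat_tubb3,
                                 dg_long_tubb4, dg_lat_tubb4) {
  vals <- c(dg_long_tubb3, dg_lat_tubb3, dg_long_tubb4, dg_lat_tubb4)
  if (!all(is.finite(vals))) stop("energies must be finite", call. = FALSE)
  structure(
    list(dg_long_tubb3 = as.numeric(dg_long_tubb3),
         dg_lat_tubb3 = as.numeric(dg_lat_tubb3),
         dg_long_tubb4 = as.numeric(dg_long_tubb4),
         dg_lat_tubb4 = as.numeric(dg_lat_tubb4)),
    class = "energy_parameter_set")
}

#' Calibrated ("refined") energy parameter set
#'
#' The energy parameter set retained after the two-stage velocity-window
#' calibration against measured axonal growth velocities:
#' dG_long(Tubb3) = -5 RT, dG_lat(Tubb3) = -3 RT, dG_long(Tubb4) = -7.5 RT,
#' dG_lat(Tubb4) = -6 RT.
#'
#' @return An `energy_parameter_set`.
#' @export
refined_energies <- function() {
  energy_parameter_set(-5, -3, -7.5, -6)
}

#' Fixed bond energies of the pooled remaining beta-tubulin isotypes
#'
#' @return Named numeric vector with elements `dg_long` (-7 RT) and
#'   `dg_lat` (-4 RT).
#' @export
other_tubb_energies <- function() {
  c(dg_long = -7, dg_lat = -4)
}

#' Build the three dimer species from energies and concentrations
#'
#' @param energies An [energy_parameter_set()].
#' @param concentrations An [isotype_concentrations()] triple (uM).
#' @return List of three `dimer_species` (Tubb3, Tubb4, other Tubbs).
#' @examples
#' make_species(refined_energies(), control_concentrations())
#' @export
make_species <- function(energies = refined_energies(),
                         concentrations = control_concentrations()) {
  stopifnot(inherits(energies, "energy_parameter_set"),
            inherits(concentrations, "isotype_concentrations"))
  other <- other_tubb_energies()
  list(
    dimer_species(1, "Tubb3", energies$dg_long_tubb3, energies$dg_lat_tubb3,
                  concentrations$c_tubb3),
    dimer_species(2, "Tubb4", energies$dg_long_tubb4, energies$dg_lat_tubb4,
                  concentrations$c_tubb4),
    dimer_species(3, "other Tubbs", other[["dg_long"]], other[["dg_lat"]],
                  concentrations$c_other))
}

# internal: species list -> parallel numeric vectors for the C++ core
species_vectors <- function(species) {
  stopifnot(is.list(species), length(species) == 3L)
  ids <- vapply(species, function(s) s$species_id, integer(1))
  if (!identical(ids, 1:3)) {
    stop("species must be given in id order 1, 2, 3", call. = FALSE)
  }
  list(dg_long = vapply(species, function(s) s$dg_long, numeric(1)),
       dg_lat = vapply(species, function(s) s$dg_lat, numeric(1)),
       conc = vapply(species, function(s) s$concentration, numeric(1)))
}
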