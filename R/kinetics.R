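#' Kinetic rate constants
#'
#' The bimolecular on-rate constant k_on (uM^-1 s^-1) applies to all dimer
#' species; multiplied by a species' free concentration it gives the
#' pseudo-first-order association rate of one protofilament tip.  Energies
#' are carried in RT units throughout, so the gas constant and temperature
#' never appear numerically; the equilibrium constant K = exp(-dG) implicitly
#' refers to a 1 uM standard state, which fixes absolute off-rate magnitudes
#' as k_off = k_on * exp(dG).
#'
#' @param k_on Bimolecular on-rate constant in uM^-1 s^-1 (default 30).
#' @param reference_concentration Standard-state concentration, uM (fixed 1).
#' @return An object of class `rate_constants`.
#' @export
rate_constants <- function(k_on = 30, reference_concentration = 1) {
  stopifnot(is.finite(k_on), k_on > 0)
  if (!identical(as.numeric(reference_concentration), 1)) {
    stop("the standard state is fixed at 1 uM", call. = FALSE)
  }
  structure(list(k_on = as.numeric(k_on), reference_concentration = 1),
            class = "rate_constants")
}

#' Steric on-rate penalty rule
#'
#' Binding into a site that already has lateral neighbors is sterically
#' hindered: the on-rate is divided by 2 for one lateral neighbor and by 10
#' for two.  The lattice seam produces fractional neighbor counts (0.5, 1.5)
#' for which no penalty is prescribed by the rate law; the default buckets a
#' partial neighbor with a full one (any obstruction on one side hinders
#' like a full dimer): divisors 1, 2, 2, 10, 10 for x = 0, 0.5, 1, 1.5, 2.
#' [penalty_rule_geometric()] provides an interpolating alternative for
#' sensitivity analysis.
#'
#' @param divisors Numeric vector of length 5: divisor for x = 0, 0.5, 1,
#'   1.5, 2.  Must be >= 1 and non-decreasing.
#' @return An object of class `penalty_rule`.
#' @export
penalty_rule <- function(divisors = c(1, 2, 2, 10, 10)) {
  stopifnot(length(divisors) == 5, all(is.finite(divisors)),
            all(divisors >= 1), !is.unsorted(divisors))
  structure(list(divisors = as.numeric(divisors)), class = "penalty_rule")
}

#' Geometric-interpolation penalty rule
#'
#' Divisor 2^x up to one neighbor, then geometric interpolation between 2
#' (x = 1) and 10 (x = 2): divisors 1, sqrt(2), 2, sqrt(20), 10.
#'
#' @return A `penalty_rule`.
#' @export
penalty_rule_geometric <- function() {
  penalty_rule(c(1, sqrt(2), 2, sqrt(20), 10))
}

#' On-rate penalty divisor for a neighbor count
#'
#' @param rule A [penalty_rule()].
#' @param x Lateral neighbor count in \{0, 0.5, 1, 1.5, 2\}.
#' @return The divisor applied to the on-rate.
#' @export
penalty_divisor <- function(rule, x) {
  stopifnot(inherits(rule, "penalty_rule"))
  i <- match(x, c(0, 0.5, 1, 1.5, 2))
  if (any(is.na(i))) stop("x must be a half-integer in [0, 2]", call. = FALSE)
  rule$divisors[i]
}

#' Free energy change of binding with x lateral neighbors
#'
#' dG = dG_long + x * dG_lat, in RT units.  One longitudinal bond is always
#' formed; each (fractional) lateral neighbor adds a proportional share of
#' the lateral bond energy.
#'
#' @param species A [dimer_species()].
#' @param x Lateral neighbor count.
#' @return Free energy change in RT units.
#' @export
binding_free_energy <- function(species, x) {
  stopifnot(inherits(species, "dimer_species"))
  species$dg_long + x * species$dg_lat
}

#' Association rate of one protofilament tip for one species
#'
#' k_on * C / divisor(x): the pseudo-first-order on-rate (s^-1), reduced by
#' the steric penalty of the binding site's current lateral neighbors.
#'
#' @param species A [dimer_species()].
#' @param x Lateral neighbor count at the binding site.
#' @param rc [rate_constants()].
#' @param pr [penalty_rule()].
#' @return Rate in s^-1 (0 when the species' concentration is 0).
#' @export
on_rate <- function(species, x, rc = rate_constants(), pr = penalty_rule()) {
  stopifnot(inherits(species, "dimer_species"), inherits(rc, "rate_constants"))
  rc$k_on * species$concentration / penalty_divisor(pr, x)
}

#' Dissociation rate of a single dimer
#'
#' k_off = k_on / exp(-dG) = k_on * exp(dG_long + x * dG_lat), energies in
#' RT units.  Strong (more negative) bonds give small rates.
#'
#' @inheritParams on_rate
#' @return Rate in s^-1.
#' @export
off_rate_single <- function(species, x, rc = rate_constants()) {
  stopifnot(inherits(species, "dimer_species"), inherits(rc, "rate_constants"))
  rc$k_on * exp(binding_free_energy(species, x))
}

#' Equilibrium constant for a binding site
#'
#' K = k_on / k_off = exp(-dG) in uM^-1 (1 uM standard state).
#'
#' @inheritParams on_rate
#' @return K in uM^-1.
#' @export
equilibrium_constant <- function(species, x, rc = rate_constants()) {
  koff <- off_rate_single(species, x, rc)
  if (koff <= 0) stop("off-rate is zero; K is unbounded", call. = FALSE)
  rc$k_on / koff
}

#' Dissociation rate of a cascade (stack) event
#'
#' Rate of the event that removes the dimer at `height` together with every
#' dimer above it on the same protofilament:
#' k_on * exp(dG_long(bottom) + sum over removed dimers of x_d * dG_lat_d).
#' Only the bottom dimer's longitudinal bond is broken by default -- the
#' stack departs as a unit -- plus all lateral bonds of the removed dimers.
#' With `include_internal_longitudinal = TRUE` the longitudinal bonds inside
#' the departing stack are also added to the exponent (a stricter reading in
#' which the stack fully disassembles); the two variants only differ
#' appreciably for laterally unbonded columns.
#'
#' @param lattice An `mt_lattice`.
#' @param pf Protofilament index.
#' @param height Occupied height of the stack's bottom dimer.
#' @param species_list List of the three `dimer_species` (id order).
#' @param rc [rate_constants()].
#' @param include_internal_longitudinal Include longitudinal bonds internal
#'   to the removed stack (default FALSE).
#' @return Rate in s^-1.
#' @export
stack_off_rate <- function(lattice, pf, height, species_list,
                           rc = rate_constants(),
                           include_internal_longitudinal = FALSE) {
  heights <- cascade_removal_set(lattice, pf, height)  # validates
  sv <- species_vectors(species_list)
  col <- lattice$columns[[pf]]
  bottom_sp <- col[heights[1]]
  expo <- sv$dg_long[bottom_sp]
  for (h in heights) {
    sp <- col[h]
    x <- lateral_neighbor_count(lattice, pf, h)
    expo <- expo + x * sv$dg_lat[sp]
    if (include_internal_longitudinal && h > heights[1]) {
      expo <- expo + sv$dg_long[sp]
    }
  }
  rc$k_on * exp(expo)
}
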