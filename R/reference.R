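# Pure-R reference implementation of the event system.  The compiled core
# is the production path; these functions expose the same event enumeration
# and first-reaction semantics step by step, for inspection and for the
# equivalence tests (they consume R's RNG in exactly the same order as the
# compiled loop, so a shared seed yields an identical trajectory).

#' Enumerate all candidate events with their rates
#'
#' For the current lattice: one binding event per (protofilament, species)
#' with positive concentration, rated by [on_rate()] at the tip binding
#' site's lateral neighbor count, followed by one cascade-dissociation event
#' per occupied dimer, rated by [stack_off_rate()].  Dissociation candidates
#' are listed tip-downward per column and scanning stops once an upper bound
#' on all deeper rates falls below `config$rate_floor` (lateral energy sums
#' only grow downward, so the bound is exact); individually sub-floor rates
#' are also skipped.
#'
#' @param lattice An `mt_lattice`.
#' @param config A [simulation_config()].
#' @return Data frame with columns `type` ("bind"/"diss"), `pf`, `species`
#'   (NA for dissociation), `height` (NA for binding) and `rate`, in the
#'   canonical enumeration order.
#' @export
enumerate_events <- function(lattice, config) {
  stopifnot(inherits(lattice, "mt_lattice"),
            inherits(config, "simulation_config"))
  sv <- species_vectors(config$species)
  n_pf <- lattice$config$n_protofilaments
  on_scale <- if (identical(config$on_rate_scope, "per_microtubule")) {
    1 / n_pf
  } else 1
  rows <- list()
  for (p in seq_len(n_pf)) {
    site <- length(lattice$columns[[p]]) + 1L
    x <- lateral_neighbor_count(lattice, p, site)
    div <- penalty_divisor(config$penalty, x)
    for (s in 1:3) {
      if (sv$conc[s] <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = "bind", pf = p, species = s, height = NA_integer_,
        rate = config$rates$k_on * sv$conc[s] * on_scale / div)
    }
  }
  dg_long_max <- max(sv$dg_long)
  for (p in seq_len(n_pf)) {
    L <- length(lattice$columns[[p]])
    if (L == 0L) next
    lat_sum <- 0
    long_sum <- 0
    for (h in seq.int(L, 1L)) {
      sp <- lattice$columns[[p]][h]
      x <- lateral_neighbor_count(lattice, p, h)
      lat_sum <- lat_sum + x * sv$dg_lat[sp]
      expo <- sv$dg_long[sp] + lat_sum +
        if (config$stack_longitudinal_bonds) long_sum else 0
      rate <- config$rates$k_on * exp(expo)
      if (rate >= config$rate_floor) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "diss", pf = p, species = NA_integer_, height = h,
          rate = rate)
      }
      if (config$stack_longitudinal_bonds) {
        long_sum <- long_sum + sv$dg_long[sp]
      }
      bound <- config$rates$k_on * exp(dg_long_max + lat_sum +
        if (config$stack_longitudinal_bonds) long_sum else 0)
      if (bound < config$rate_floor) break
    }
  }
  if (!length(rows)) {
    return(data.frame(type = character(), pf = integer(),
                      species = integer(), height = integer(),
                      rate = numeric()))
  }
  do.call(rbind, rows)
}

#' Exponential waiting time of one event
#'
#' t = -ln(u) / rate; a zero-rate event is disabled (infinite time).
#'
#' @param rate Event rate in s^-1 (>= 0).
#' @param u Uniform random number in (0, 1].
#' @return Waiting time in s.
#' @export
sample_event_time <- function(rate, u) {
  stopifnot(rate >= 0, u > 0, u <= 1)
  if (rate == 0) return(Inf)
  -log(u) / rate
}

#' Execute one first-reaction step (reference implementation)
#'
#' Draws a fresh uniform per enumerated event, in enumeration order, and
#' executes the event with the minimum waiting time (ties, which occur with
#' probability zero, go to the earlier event).
#'
#' @param lattice An `mt_lattice`.
#' @param config A [simulation_config()].
#' @return List with the updated `lattice`, the executed `event` (one row of
#'   [enumerate_events()] output) and the elapsed time `t`; or `NULL` if no
#'   event is executable (absorbed state).
#' @export
step_first_reaction <- function(lattice, config) {
  ev <- enumerate_events(lattice, config)
  if (!nrow(ev)) return(NULL)
  times <- vapply(ev$rate, function(r) sample_event_time(r, stats::runif(1)),
                  numeric(1))
  i <- which.min(times)
  e <- ev[i, ]
  lattice <- if (e$type == "bind") {
    add_dimer(lattice, e$pf, e$species)
  } else {
    remove_cascade(lattice, e$pf, e$height)
  }
  list(lattice = lattice, event = e, t = times[i])
}

# Full reference run: same initialisation and stepping as the compiled core,
# usable to cross-check it event for event.  Internal (slow; tests only).
run_simulation_r <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  sv <- species_vectors(config$species)
  set.seed(as.integer(seed))
  n_pf <- config$lattice$n_protofilaments
  start <- config$lattice$start_length
  conc_total <- sum(sv$conc)
  cols <- vector("list", n_pf)
  for (p in seq_len(n_pf)) {
    cols[[p]] <- vapply(seq_len(start), function(h) {
      u <- stats::runif(1)
      if (identical(config$start_composition, "uniform") || conc_total <= 0) {
        min(3L, as.integer(u * 3) + 1L)
      } else {
        min(3L, findInterval(u, cumsum(sv$conc / conc_total),
                             left.open = TRUE) + 1L)
      }
    }, integer(1))
  }
  lattice <- new_lattice(config$lattice, cols)
  total_time <- 0
  n_bind <- 0L
  n_diss <- 0L
  truncated <- FALSE
  steps <- 0L
  for (k in seq_len(config$n_events)) {
    st <- step_first_reaction(lattice, config)
    if (is.null(st)) {
      truncated <- TRUE
      break
    }
    lattice <- st$lattice
    total_time <- total_time + st$t
    if (st$event$type == "bind") n_bind <- n_bind + 1L else n_diss <- n_diss + 1L
    steps <- steps + 1L
  }
  lengths <- column_lengths(lattice)
  comp <- vapply(1:3, function(s) {
    sum(vapply(lattice$columns, function(cl) sum(cl == s), numeric(1)))
  }, numeric(1))
  raw <- list(total_time = total_time, lengths = lengths,
              composition_counts = comp, added_counts = NA,
              n_binding_events = n_bind, n_dissociation_events = n_diss,
              n_dimers_removed = NA, steps_done = steps,
              truncated = truncated, columns = lattice$columns)
  finalize_result(raw, config, seed)
}
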