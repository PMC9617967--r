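test_that("event enumeration counts binding and dissociation channels", {
  cfg_empty <- simulation_config(
    test_species(), lattice = lattice_config(start_length = 0),
    rate_floor = 0)
  lat <- new_lattice(cfg_empty$lattice)
  ev <- enumerate_events(lat, cfg_empty)
  expect_equal(sum(ev$type == "bind"), 39)   # 13 protofilaments x 3 species
  expect_equal(sum(ev$type == "diss"), 0)

  cfg <- simulation_config(test_species(), rate_floor = 0)
  lat10 <- new_lattice(cfg$lattice, rep(list(rep(3L, 10)), 13))
  ev10 <- enumerate_events(lat10, cfg)
  expect_equal(sum(ev10$type == "bind"), 39)
  expect_equal(sum(ev10$type == "diss"), 130)  # one per occupied dimer

  # a zero-concentration species contributes no binding channels
  cfg0 <- simulation_config(test_species(c4 = 0), rate_floor = 0)
  ev0 <- enumerate_events(lat10, cfg0)
  expect_equal(sum(ev0$type == "bind"), 26)
  expect_false(any(ev0$species == 2, na.rm = TRUE))
})

test_that("the rate floor drops only negligible dissociation propensity", {
  cfg_exact <- simulation_config(test_species(), rate_floor = 0)
  cfg_floor <- simulation_config(test_species(), rate_floor = 1e-12)
  lat <- new_lattice(cfg_exact$lattice, rep(list(rep(3L, 10)), 13))
  exact <- enumerate_events(lat, cfg_exact)
  floored <- enumerate_events(lat, cfg_floor)
  expect_lt(nrow(floored), nrow(exact))
  rel_err <- (sum(exact$rate) - sum(floored$rate)) / sum(exact$rate)
  expect_lt(rel_err, 1e-9)
})

test_that("event waiting times follow t = -ln(u)/rate", {
  expect_equal(sample_event_time(5, 1), 0)
  expect_equal(sample_event_time(2, exp(-1)), 0.5)
  expect_identical(sample_event_time(0, 0.3), Inf)
  expect_error(sample_event_time(-1, 0.5))
})

test_that("first-reaction sampling matches the Gillespie direct method", {
  # frozen small lattice: selection frequencies must follow rate/sum(rates)
  # and the winning time must be Exp(sum(rates))
  cfg <- simulation_config(test_species(),
                           lattice = lattice_config(n_protofilaments = 3,
                                                    start_length = 2))
  lat <- new_lattice(cfg$lattice, rep(list(c(1L, 3L)), 3))
  ev <- enumerate_events(lat, cfg)
  set.seed(901)
  draws <- frm_draws(ev$rate, 20000)
  expected <- direct_method_probs(ev$rate) * 20000
  keep <- expected >= 5  # chi-square validity
  chisq <- sum((tabulate(draws$index, nrow(ev))[keep] - expected[keep])^2 /
                 expected[keep])
  expect_lt(chisq, stats::qchisq(0.99, df = sum(keep) - 1))
  ks <- stats::ks.test(draws$time, "pexp", rate = sum(ev$rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("step executes the minimum-time event with first-reaction semantics", {
  # two equal-rate binding channels (equal-concentration species racing for
  # the same tip) are selected equally often
  cfg <- simulation_config(test_species(2, 2, 0),
                           lattice = lattice_config(n_protofilaments = 1,
                                                    start_length = 1))
  lat <- new_lattice(cfg$lattice, list(2L))
  set.seed(77)
  picks <- replicate(3000, {
    st <- step_first_reaction(lat, cfg)
    if (st$event$type == "bind") st$event$species else NA
  })
  picks <- picks[!is.na(picks)]
  expect_gt(length(picks), 2500)
  bt <- stats::binom.test(sum(picks == 1), length(picks), 0.5)
  expect_gt(bt$p.value, 0.001)
  # a dissociation at height h truncates the column to h - 1
  lat2 <- new_lattice(lattice_config(n_protofilaments = 2, start_length = 4),
                      rep(list(rep(3L, 4)), 2))
  cfg2 <- simulation_config(
    test_species(0, 0, 0), lattice = lat2$config,
    start_composition = "uniform")
  st2 <- step_first_reaction(lat2, cfg2)  # only dissociations possible
  expect_equal(st2$event$type, "diss")
  expect_equal(length(st2$lattice$columns[[st2$event$pf]]),
               st2$event$height - 1)
})

test_that("compiled runs replay the reference implementation event for event", {
  cfg <- simulation_config(
    test_species(),
    lattice = lattice_config(n_protofilaments = 5, start_length = 4),
    n_events = 60)
  for (seed in c(1, 902)) {
    a <- run_simulation(cfg, seed)
    b <- mtkmc:::run_simulation_r(cfg, seed)
    expect_identical(a$lengths, b$lengths)
    expect_identical(lapply(a$columns, as.integer), b$columns)
    expect_equal(a$total_time, b$total_time, tolerance = 1e-12)
    expect_equal(a$n_binding_events, b$n_binding_events)
    expect_equal(a$n_dissociation_events, b$n_dissociation_events)
  }
  # the uniform start-composition switch is honored identically
  cfg_u <- simulation_config(
    test_species(), lattice = cfg$lattice, n_events = 40,
    start_composition = "uniform")
  expect_identical(run_simulation(cfg_u, 7)$lengths,
                   mtkmc:::run_simulation_r(cfg_u, 7)$lengths)
})

test_that("identical config and seed reproduce a run exactly", {
  cfg <- simulation_config(test_species(), n_events = 300)
  a <- run_simulation(cfg, 123)
  b <- run_simulation(cfg, 123)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$total_time, b$total_time)
  expect_identical(a$composition_counts, b$composition_counts)
  c <- run_simulation(cfg, 124)
  expect_false(identical(a$lengths, c$lengths) &&
                 identical(a$total_time, c$total_time))
})

test_that("species with zero concentration never appear among added dimers", {
  cfg <- simulation_config(test_species(c3 = 0), n_events = 400)
  r <- run_simulation(cfg, 5)
  expect_equal(r$added_counts[1], 0)
  expect_equal(r$composition_counts[1], 0)  # proportional start excludes it
})

test_that("with all concentrations zero only dissociation occurs until absorption", {
  cfg <- simulation_config(test_species(0, 0, 0), n_events = 500,
                           start_composition = "uniform")
  r <- run_simulation(cfg, 9)
  expect_true(r$truncated)
  expect_equal(r$n_binding_events, 0)
  expect_true(all(r$added_per_pf <= 0))
  expect_equal(sum(r$lengths), 0)  # fully depolymerized, then absorbed
})

test_that("growth velocity converts net dimers per time to um/s", {
  lc <- lattice_config()
  expect_equal(growth_velocity(100, 4, lc), 0.2)  # 100 x 8 nm / 4 s
  expect_equal(growth_velocity(0, 10, lc), 0)
  lc2 <- lattice_config(dimer_length = 16)
  expect_equal(growth_velocity(100, 4, lc2), 0.4)  # linear in dimer length
  expect_error(growth_velocity(10, 0, lc), "total_time")
})

test_that("velocity baseline convention: zero net addition gives zero velocity", {
  cfg <- simulation_config(test_species(), n_events = 50)
  r <- run_simulation(cfg, 31)
  direct <- mean(r$lengths - cfg$lattice$start_length) *
    cfg$lattice$dimer_length / 1000 / r$total_time
  expect_equal(r$velocity, direct)
  cfg_ns <- simulation_config(test_species(), n_events = 50,
                              subtract_start_length = FALSE)
  r_ns <- run_simulation(cfg_ns, 31)
  expect_equal(r_ns$velocity,
               mean(r_ns$lengths) * 8 / 1000 / r_ns$total_time)
})

test_that("composition fractions sum to one and degenerate cases behave", {
  cfg <- simulation_config(test_species(), n_events = 200)
  f <- composition_fractions(run_simulation(cfg, 2))
  expect_equal(sum(f), 1)
  expect_named(f, c("tubb3", "tubb4", "other"))
  # a single present species owns the lattice
  cfg1 <- simulation_config(test_species(0, 0, 4.06), n_events = 100)
  expect_equal(unname(composition_fractions(run_simulation(cfg1, 3))[3]), 1)
})

test_that("replicate statistics report the velocity sample with SEM = sd/sqrt(n)", {
  cfg <- simulation_config(test_species(), n_events = 200)
  rs <- replicate_stats(cfg, 8, seed = 99)
  expect_length(rs$velocities, 8)
  expect_equal(rs$mean, mean(rs$velocities))
  expect_equal(rs$sem, stats::sd(rs$velocities) / sqrt(8))
  # child seeds are a pure function of the master seed
  expect_identical(rs$seeds, derive_seeds(99, 8))
  rs2 <- replicate_stats(cfg, 8, seed = 99)
  expect_identical(rs$velocities, rs2$velocities)
})

test_that("single-protofilament growth matches the birth-death chain prediction", {
  # 1 protofilament, one species: no lateral bonds, no penalties.  With the
  # stack variant that counts internal longitudinal bonds, removals deeper
  # than the tip are suppressed by e^{dG_long} per extra dimer, so the tip
  # is a birth-death chain: v = (k_on C - k_on e^{dG_long}) * dimer_length.
  dgl <- -5
  conc <- 0.05
  cfg <- simulation_config(
    make_species(energy_parameter_set(-9, -1, -9, -1),
                 isotype_concentrations(0, 0, conc)),
    lattice = lattice_config(n_protofilaments = 1, start_length = 10),
    n_events = 400, stack_longitudinal_bonds = TRUE)
  # override the fixed other-Tubb energies for this oracle check
  cfg$species[[3]]$dg_long <- dgl
  cfg$species[[3]]$dg_lat <- -1
  rs <- replicate_stats(cfg, 200, seed = 4)
  predicted <- (30 * conc - 30 * exp(dgl)) * 8 / 1000
  expect_lt(abs(rs$mean - predicted), 3 * rs$sem)

  # pure-growth regime: dissociation negligible, v = k_on C dimer_length
  cfg2 <- simulation_config(
    make_species(energy_parameter_set(-9, -1, -9, -1),
                 isotype_concentrations(0, 0, 0.2)),
    lattice = lattice_config(n_protofilaments = 1, start_length = 10),
    n_events = 400, stack_longitudinal_bonds = TRUE)
  cfg2$species[[3]]$dg_long <- -14
  rs2 <- replicate_stats(cfg2, 100, seed = 5)
  expect_lt(abs(rs2$mean - 30 * 0.2 * 8 / 1000), 3 * rs2$sem)
})

test_that("strengthening bonds does not slow growth (statistical monotonicity)", {
  run_mean <- function(dgl3, dgt3, n = 60) {
    cfg <- simulation_config(
      make_species(energy_parameter_set(dgl3, dgt3, -7.5, -6),
                   isotype_concentrations(3, 1, 3)),
      n_events = 800)
    replicate_stats(cfg, n, seed = 17)
  }
  weak <- run_mean(-3, -1)
  mid <- run_mean(-5, -3)
  strong <- run_mean(-8, -6)
  tol <- function(a, b) 3 * sqrt(a$sem^2 + b$sem^2)
  expect_gt(mid$mean - weak$mean, -tol(mid, weak))
  expect_gt(strong$mean - mid$mean, -tol(strong, mid))
})
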