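---
title: "A kinetic Monte Carlo model of microtubule growth with tubulin isotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic Monte Carlo model of microtubule growth with tubulin isotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mtkmc)
```

## The model

`mtkmc` simulates the growing plus end of a microtubule as a two-dimensional
sheet of 13 protofilament columns.  Each cell of the sheet is one
alpha/beta-tubulin heterodimer, drawn from three species: Tubb3-containing
dimers, Tubb4-containing dimers, and a pooled class for the remaining
beta-tubulin isotypes (free energy changes are additive, so a single
effective species can absorb the rest).  Lateral adjacency is periodic; the
seam between the last protofilament and the first carries a 1.5-dimer axial
stagger, so contacts across it contribute half neighbors and a dimer can
have 0, 0.5, 1, 1.5 or 2 lateral neighbors.  Catastrophe, shrinkage, rescue
and GTP hydrolysis are outside the model's scope: it describes the growth
phase only.

Binding and unbinding at a site with `x` lateral neighbors are governed by
a standard thermodynamic cycle.  With energies in RT units,

* free energy change of binding: `dG = dG_long + x * dG_lat`,
* association: `k_on * C / penalty(x)` per protofilament tip, with
  `k_on = 30` per uM per s and `C` the species' free concentration,
* dissociation: `k_off = k_on * exp(dG)`, the detailed-balance partner of
  the association rate at the 1 uM standard state,
* steric penalty: binding into a site that already has lateral neighbors
  is slowed, by 2 for one neighbor and by 10 for two.

A dimer inside a column can also leave: it takes every dimer above it with
it (cascade, or stack, dissociation).  The departing stack breaks the
bottom dimer's longitudinal bond plus all lateral bonds of its members,
which is the default rate law here; a stricter variant that also counts
the longitudinal bonds internal to the stack is available as
`stack_longitudinal_bonds = TRUE` and matters only for laterally unbonded
columns.

Trajectories use the first-reaction method: every candidate event (three
binding channels per protofilament tip, one cascade channel per occupied
dimer) draws an exponential waiting time `-log(U)/rate` and the minimum
executes; 5,000 events make one run.  Velocity is the mean protofilament
length gained, net of the 10-dimer seed columns, times the 8 nm dimer
length, divided by elapsed time.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_on` | 30 uM^-1 s^-1 | bimolecular on-rate constant, all species |
| `dG_long`, `dG_lat` | -5/-3 (Tubb3), -7.5/-6 (Tubb4), -7/-4 (others) RT | bond free energies; the first two pairs are the calibrated values |
| `C` | 0.98 / 1.96 / 4.06 uM | control concentrations: 14/28/58% of a 7 uM pool |
| `n_events` | 5000 | events per run |
| `start_length` | 10 dimers | seed column height, so dissociation is possible immediately |
| `dimer_length` | 8 nm | axial dimer repeat, converts dimers/s to um/s |
| `rate_floor` | 1e-12 s^-1 | cascade channels below this are skipped (relative propensity error < 1e-9) |

Knockdown concentrations scale Tubb3 expression to 43% and Tubb4 to 133%
of control with the 7 uM pool conserved, giving 0.42/2.61/3.97 uM; the
residual class absorbs the difference.  The hypothetical expression
scenarios I-IV are stored literally (2.1/0.84/4.06, 0.98/0.84/5.18,
0.98/2.61/4.06, 2.1/1.96/4.06 uM); note that III and IV change the total
pool.

## Numerical and design choices

Several places in the model admit more than one reading; the package fixes
one default each and keeps the alternative behind a configuration switch,
so their effect can be measured rather than argued about.

* **On-rate scope.**  "Each protofilament binds" is read as three
  pseudo-first-order channels of `k_on * C` per tip
  (`on_rate_scope = "per_protofilament"`).  The alternative, splitting one
  microtubule-wide propensity across the 13 tips, scales velocities down
  about 13-fold and is kept as `"per_microtubule"`.
* **Fractional-neighbor penalties.**  The penalty rule is prescribed only
  at x = 1 (divide by 2) and x = 2 (divide by 10).  The default buckets a
  half neighbor with the next full one (1, 2, 2, 10, 10 for x = 0, 0.5, 1,
  1.5, 2), treating any obstruction on a side as that side blocked;
  `penalty_rule_geometric()` interpolates instead.  The difference only
  touches seam sites.
* **Velocity baseline.**  The 10-dimer seed is subtracted before dividing
  by time, so a run with zero net growth reports zero velocity.  The
  non-subtracted variant (`subtract_start_length = FALSE`) differs by
  about 3% on a 5,000-event run.
* **Seed columns.**  Start-column dimers are sampled proportionally to the
  species concentrations; `start_composition = "uniform"` gives the
  equal-thirds alternative.
* **Tie-breaking.**  Equal minimum waiting times (probability zero) go to
  the earlier event in the canonical enumeration order, documented so that
  trajectories are bit-reproducible.
* **Empty columns.**  Columns may shrink below the seed length, down to
  zero, and can re-nucleate from the base; no artificial floor is imposed.
* **Randomness.**  All draws flow through R's generator.  A master seed
  expands to per-replicate child seeds (`derive_seeds()`) drawn once, so
  replicate k gets the same seed regardless of evaluation order; run
  manifests record them.

The compiled core consumes one uniform per enumerated event in a fixed
order, and the pure-R reference implementation (`enumerate_events()`,
`step_first_reaction()`) consumes the identical stream: the test suite
replays compiled trajectories event for event against the reference, and
checks the first-reaction statistics against the Gillespie direct method
(selection frequencies proportional to rates, exponential total waiting
time).  A further oracle check runs a single protofilament, where the tip
is a birth-death chain with closed-form velocity
`(k_on C - k_on e^{dG_long}) * dimer_length`; this regime needs the
internal-longitudinal stack variant, since with the default (lateral-only)
stack energies an isolated column would dissociate equally fast from every
height.

## Energy calibration

The bond energies of Tubb3 and Tubb4 are the model's only fitted
quantities.  `grid_points()` spans longitudinal energies from -3 to -9 RT
in 0.5 RT steps and lateral energies from -1 RT down to the longitudinal
value (143 pairs per isotype, 20,449 4-tuples); lateral bonds stronger
than longitudinal ones are excluded as unstable.  `evaluate_grid()`
simulates every set under control and knockdown concentrations,
`filter_by_windows()` keeps sets whose means fall inside the measured
windows (first pass 0.167 +/- 0.006 and 0.201 +/- 0.008 um/s), and
`refine()` re-scores survivors at 100 replicates against the tighter +/-
0.002 windows.  `contour_grid()` exports the velocity landscape of one
isotype's energy plane with the other fixed, the layout used to display
such scans.

## Problem sizes

Full-scale results in this package mean 400 replicates of 5,000 events
for velocity means (SEM near the per-mille level) and 100 replicates for
composition and SEM summaries; `scripts/acceptance.R` recomputes all of
them at that scale.  The test suite exercises the same code paths at
reduced replication (tens of replicates, hundreds to thousands of events)
and the scan check uses a small neighborhood of the calibrated set rather
than all 20,449 points; these sizes are chosen so the whole suite runs in
minutes while keeping Monte Carlo error well inside the asserted
tolerances.

## What the model does and does not reproduce

Within this implementation the calibrated energies behave coherently: the
four near-equivalent calibrated parameter sets give near-identical
velocities here too (they share the combination `dG_long + dG_lat`, the
energy of a singly laterally bonded dimer), knockdown concentrations grow
faster than control for all of them, and scenario I (Tubb4 replaced by
Tubb3) is the slowest condition, as measured.

The absolute scale does not match the reference measurements, and the
package reports this honestly rather than absorbing it into a fudge
factor.  Under the default reading the control condition grows at about
0.47 um/s where 0.167 um/s was measured, and the Tubb3 share of the
lattice stays near its 14% supply share instead of dropping to ~4%.  The
two mismatches are linked: at `k_on * C` tip fluxes of order 100 s^-1 and
off-rates bounded by `30 e^{-5} ~ 0.2` s^-1, a newly bound dimer is buried
long before it can dissociate, so growth is flux-limited and barely
isotype-selective.  Strong selection would require off-rates comparable to
the binding flux, which the stated energies cannot produce; no combination
of the documented alternative readings (on-rate scope, stack energy,
penalty interpolation, baseline, seed composition) changes this, as each
either rescales both conditions together or perturbs velocities by a few
percent.  Consequently velocity windows centered on the measured values
select no parameter set in this implementation, and the composition,
scenario-velocity and SEM figures recomputed by `scripts/acceptance.R`
sit at the model's own scale.  The qualitative predictions above are the
part of the science this implementation supports.

## Limitations

The model is a growth-phase caricature: no catastrophe or rescue, no
GTP/GDP state, no mechanics, an infinite free-dimer reservoir, and a
two-dimensional sheet standing in for the closed tube.  Velocities scale
linearly with the assumed 8 nm dimer repeat.  Composition fractions count
the final lattice including the seeded columns.  The first-reaction
method is exact but draws one uniform per candidate event, so runs are
reproducible only under the documented enumeration order and rate floor.
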