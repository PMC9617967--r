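# Shared fixtures and independent oracles, built in code.

# Three species with distinct, easily recognisable energetics.
test_species <- function(c3 = 0.98, c4 = 1.96, co = 4.06) {
  make_species(refined_energies(), isotype_concentrations(c3, c4, co))
}

# A small lattice with hand-set columns (3 protofilaments unless stated).
small_lattice <- function(columns, n_pf = length(columns), start_length = 0) {
  new_lattice(lattice_config(n_protofilaments = n_pf,
                             start_length = start_length), columns)
}

# Independent interval-overlap computation of the lateral neighbor count:
# dimers are unit intervals [h-1, h] along each column.  Across an aligned
# edge the two columns share one frame; across the seam edge (last column
# vs column 1) the last column is raised by 1.5.  Sums the overlap of the
# queried site with every occupied interval of the two adjacent columns.
# Shares no code with the implementation.
overlap_neighbor_count <- function(lattice, pf, height) {
  n <- lattice$config$n_protofilaments
  if (n == 1) return(0)
  total <- 0
  for (q in c(pf - 1, pf + 1)) {
    qq <- ((q - 1) %% n) + 1
    # relative raise of the queried column w.r.t. the neighbor on this edge;
    # the seam is the wrapping edge (unwrapped q outside 1..n)
    rel <- if (q == n + 1) 1.5 else if (q == 0) -1.5 else 0
    site <- c(height - 1, height) + rel
    for (h in seq_along(lattice$columns[[qq]])) {
      iv <- c(h - 1, h)
      total <- total + max(0, min(site[2], iv[2]) - max(site[1], iv[1]))
    }
  }
  total
}

# Gillespie direct-method oracle for one step on a frozen lattice: event
# selected with probability rate/sum(rates), waiting time ~ Exp(sum(rates)).
direct_method_probs <- function(rates) rates / sum(rates)

# First-reaction draws on a frozen rate vector: fresh uniform per event,
# minimum wins.  Returns selected indices and minimum times.
frm_draws <- function(rates, n_draws) {
  k <- length(rates)
  u <- matrix(stats::runif(n_draws * k), nrow = n_draws)
  times <- -log(u) / rep(rates, each = n_draws)
  idx <- max.col(-times, ties.method = "first")
  list(index = idx, time = times[cbind(seq_len(n_draws), idx)])
}
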