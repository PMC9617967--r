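#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First-reaction kinetic Monte Carlo core for microtubule growth.
//
// The lattice is a set of gap-free protofilament columns; lateral adjacency
// is periodic, with the seam between the last protofilament and the first
// (the last column is raised by +1.5 dimer units relative to the first, so
// seam contacts contribute fractional lateral neighbors of 0.5 each).
//
// All random numbers come from R's generator (unif_rand), one uniform per
// enumerated event per step, in a fixed enumeration order:
//   1. binding events: pf 1..n, species 1..3 (skipped when rate is 0)
//   2. stack-dissociation events: pf 1..n, heights from tip downward,
//      truncated once an upper bound on the remaining rates drops below
//      rate_floor (every deeper height is then provably below the floor).
// The minimum-time event executes; ties (measure zero) go to the first
// event in enumeration order.
//
// Energies are in RT units (dimensionless); concentrations in uM;
// k_on in uM^-1 s^-1.

namespace {

struct Lattice {
  int n_pf;
  std::vector<std::vector<int>> col;  // species index 0..2 per height (1-based height h -> col[p][h-1])

  bool occupied(int p, int h) const {
    if (p < 0 || p >= n_pf) return false;
    return h >= 1 && h <= (int)col[p].size();
  }

  // Lateral neighbor count, in half units (2x), for the site (p, h).
  // p is 0-based; h is 1-based.  The site need not be occupied.
  int x2(int p, int h) const {
    if (n_pf == 1) return 0;
    int v = 0;
    // left edge: between p-1 and p
    if (p == 0) {
      // seam side: neighbor is the last protofilament, raised by +1.5
      int q = n_pf - 1;
      v += occupied(q, h - 2) ? 1 : 0;
      v += occupied(q, h - 1) ? 1 : 0;
    } else {
      v += occupied(p - 1, h) ? 2 : 0;
    }
    // right edge: between p and p+1
    if (p == n_pf - 1) {
      // seam side: this protofilament is raised by +1.5 relative to pf 1
      int q = 0;
      v += occupied(q, h + 1) ? 1 : 0;
      v += occupied(q, h + 2) ? 1 : 0;
    } else {
      v += occupied(p + 1, h) ? 2 : 0;
    }
    return v;
  }
};

}  // namespace

// [[Rcpp::export(name = ".kmc_run_cpp")]]
List kmc_run_cpp(NumericVector dg_long, NumericVector dg_lat,
                 NumericVector conc, double k_on, NumericVector penalty,
                 int n_pf, int start_length, int n_events, double rate_floor,
                 bool start_uniform, bool per_mt_on_rate,
                 bool stack_longitudinal) {
  const int n_sp = dg_long.size();
  Lattice lat;
  lat.n_pf = n_pf;
  lat.col.assign(n_pf, std::vector<int>());

  RNGScope scope;

  double conc_total = 0.0;
  for (int s = 0; s < n_sp; ++s) conc_total += conc[s];

  // Seed columns: start_length dimers each, species sampled either
  // uniformly across types or proportionally to free concentration.
  for (int p = 0; p < n_pf; ++p) {
    lat.col[p].reserve(start_length + n_events + 1);
    for (int h = 0; h < start_length; ++h) {
      double u = unif_rand();
      int s = 0;
      if (start_uniform || conc_total <= 0.0) {
        s = (int)(u * n_sp);
        if (s >= n_sp) s = n_sp - 1;
      } else {
        double acc = 0.0;
        for (s = 0; s < n_sp; ++s) {
          acc += conc[s] / conc_total;
          if (u <= acc) break;
        }
        if (s >= n_sp) s = n_sp - 1;
      }
      lat.col[p].push_back(s);
    }
  }

  // Least negative longitudinal energy: used for the early-exit bound in
  // the downward dissociation scan (lateral terms only make rates smaller).
  double dg_long_max = dg_long[0];
  for (int s = 1; s < n_sp; ++s)
    if (dg_long[s] > dg_long_max) dg_long_max = dg_long[s];

  const double on_scale = per_mt_on_rate ? 1.0 / n_pf : 1.0;

  double total_time = 0.0;
  long n_bind = 0, n_diss = 0, n_removed = 0;
  std::vector<long> added(n_sp, 0);
  bool truncated = false;
  int steps_done = 0;

  for (int step = 0; step < n_events; ++step) {
    double t_min = R_PosInf;
    int ev_type = -1, ev_pf = -1, ev_aux = -1;  // aux: species (bind) or height (diss)

    // 1. binding events, one per (protofilament, species)
    for (int p = 0; p < n_pf; ++p) {
      int tip_site = (int)lat.col[p].size() + 1;
      int x2b = lat.x2(p, tip_site);
      double div = penalty[x2b];
      for (int s = 0; s < n_sp; ++s) {
        if (conc[s] <= 0.0) continue;
        double rate = k_on * conc[s] * on_scale / div;
        double u = unif_rand();
        double t = -std::log(u) / rate;
        if (t < t_min) {
          t_min = t;
          ev_type = 0;
          ev_pf = p;
          ev_aux = s;
        }
      }
    }

    // 2. stack-dissociation events, one per occupied dimer (tip downward)
    for (int p = 0; p < n_pf; ++p) {
      int L = (int)lat.col[p].size();
      double lat_sum = 0.0;   // sum over removed dimers of x_d * dG_lat(species_d)
      double long_sum = 0.0;  // longitudinal bonds internal to the stack (optional)
      for (int h = L; h >= 1; --h) {
        int sp = lat.col[p][h - 1];
        lat_sum += 0.5 * lat.x2(p, h) * dg_lat[sp];
        double expo = dg_long[sp] + lat_sum + (stack_longitudinal ? long_sum : 0.0);
        double rate = k_on * std::exp(expo);
        if (rate >= rate_floor) {
          double u = unif_rand();
          double t = -std::log(u) / rate;
          if (t < t_min) {
            t_min = t;
            ev_type = 1;
            ev_pf = p;
            ev_aux = h;
          }
        }
        // Bound on every deeper rate: lat_sum only decreases (energies <= 0),
        // so k_on * exp(dg_long_max + lat_sum (+ long_sum)) bounds them all.
        if (stack_longitudinal) long_sum += dg_long[sp];
        double bound = k_on * std::exp(dg_long_max + lat_sum +
                                       (stack_longitudinal ? long_sum : 0.0));
        if (bound < rate_floor) break;
      }
    }

    if (ev_type < 0) {  // absorbed: nothing can bind or dissociate
      truncated = true;
      break;
    }

    if (ev_type == 0) {
      lat.col[ev_pf].push_back(ev_aux);
      ++n_bind;
      ++added[ev_aux];
    } else {
      int L = (int)lat.col[ev_pf].size();
      n_removed += L - ev_aux + 1;
      lat.col[ev_pf].resize(ev_aux - 1);
      ++n_diss;
    }
    total_time += t_min;
    ++steps_done;
  }

  IntegerVector lengths(n_pf);
  IntegerVector comp(n_sp);
  for (int p = 0; p < n_pf; ++p) {
    lengths[p] = (int)lat.col[p].size();
    for (int sp : lat.col[p]) ++comp[sp];
  }
  List cols(n_pf);
  for (int p = 0; p < n_pf; ++p) {
    IntegerVector cv(lat.col[p].size());
    for (size_t i = 0; i < lat.col[p].size(); ++i) cv[i] = lat.col[p][i] + 1;
    cols[p] = cv;
  }

  return List::create(
      _["total_time"] = total_time, _["lengths"] = lengths,
      _["composition_counts"] = comp, _["added_counts"] = IntegerVector(added.begin(), added.end()),
      _["n_binding_events"] = (double)n_bind,
      _["n_dissociation_events"] = (double)n_diss,
      _["n_dimers_removed"] = (double)n_removed,
      _["steps_done"] = steps_done, _["truncated"] = truncated,
      _["columns"] = cols);
}
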