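// Right-hand side of the isotopomer ODE system.
//
// The R layer compiles a scheme into a flat "program": for every reaction,
// consume units (substrate isotopomers drained proportionally to their
// fractional abundance) and produce units (product isotopomer distributions
// assembled as OR-convolutions of independent parts, one part per substrate
// contributing carbons to that product). Scramble variants appear as
// weighted duplicate produce units. The program arrives as flat integer /
// double vectors so the hot loop touches no R objects by name.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector isotopomer_rhs_cpp(NumericVector state, NumericVector fluxes,
                                 List program) {
  IntegerVector offsets = program["offsets"];   // 0-based, per tracked pool
  IntegerVector sizes = program["sizes"];       // 2^n per tracked pool
  List flat = program["flat"];
  IntegerVector u_kind = flat["u_kind"];        // 0 consume, 1 produce
  IntegerVector u_pool = flat["u_pool"];        // 0-based pool index
  IntegerVector u_rate = flat["u_rate"];        // 0-based flux index
  NumericVector u_weight = flat["u_weight"];
  IntegerVector u_part0 = flat["u_part0"];      // first part of unit (0-based)
  IntegerVector u_nparts = flat["u_nparts"];
  IntegerVector p_src = flat["p_src"];          // 0-based pool; -1 Bernoulli
  IntegerVector p_mask = flat["p_mask"];
  NumericVector p_q = flat["p_q"];
  IntegerVector p_proj0 = flat["p_proj0"];      // offset into proj_all
  IntegerVector proj_all = flat["proj_all"];

  int npool = offsets.size();
  int n = state.size();
  NumericVector dx(n);

  // fractional isotopomer abundances per pool; empty pool = delta at zero
  std::vector<std::vector<double>> frac(npool);
  for (int p = 0; p < npool; ++p) {
    int off = offsets[p], sz = sizes[p];
    double tot = 0.0;
    for (int i = 0; i < sz; ++i) tot += state[off + i];
    frac[p].assign(sz, 0.0);
    if (tot > 1e-12) {
      for (int i = 0; i < sz; ++i) frac[p][i] = state[off + i] / tot;
    } else {
      frac[p][0] = 1.0;
    }
  }

  int nunits = u_kind.size();
  std::vector<double> part_dist;
  std::vector<double> acc;
  for (int u = 0; u < nunits; ++u) {
    double v = u_weight[u] * fluxes[u_rate[u]];
    if (v == 0.0) continue;
    int poolIdx = u_pool[u];
    int off = offsets[poolIdx], sz = sizes[poolIdx];
    if (u_kind[u] == 0) {                         // consume
      const std::vector<double>& f = frac[poolIdx];
      for (int i = 0; i < sz; ++i) dx[off + i] -= v * f[i];
    } else {                                      // produce
      acc.assign(sz, v);
      int j0 = u_part0[u], j1 = j0 + u_nparts[u];
      for (int j = j0; j < j1; ++j) {
        int src = p_src[j];
        int mask = p_mask[j];
        part_dist.assign(sz, 0.0);
        if (src >= 0) {
          const std::vector<double>& f = frac[src];
          int ssz = sizes[src];
          const int* proj = &proj_all[p_proj0[j]];
          for (int s = 0; s < ssz; ++s) part_dist[proj[s]] += f[s];
        } else {
          double q = p_q[j];
          part_dist[0] += 1.0 - q;
          part_dist[mask] += q;
        }
        for (int k = 0; k < sz; ++k) acc[k] *= part_dist[k & mask];
      }
      for (int k = 0; k < sz; ++k) dx[off + k] += acc[k];
    }
  }
  return dx;
}
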