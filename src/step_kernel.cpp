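#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One simulated time step consists of two passes over the terminals, both in
// neuron-id order so that the stream of RNG draws is fully determined:
//   1. every unoccupied terminal extends by step_length at a uniform random
//      angle (one draw per terminal), reflecting at the sheet boundary, and
//      becomes eligible once its position leaves the parent area;
//   2. every unoccupied, eligible terminal with at least one soma closer
//      than contact_radius picks the nearest candidate (uniform draw only on
//      exact distance ties, tied candidates in soma-id order) and occupies
//      it with probability accept_prob (one draw per candidate-holding
//      terminal).
// All draws come from R's RNG (unif_rand), so results are reproducible from
// set.seed() and bit-identical to the reference R implementation.

static inline double reflect1(double v, double lo, double hi) {
  // mirror reflection into [lo, hi]; step lengths are small relative to the
  // sheet, but loop for safety
  for (int guard = 0; guard < 64; ++guard) {
    if (v < lo) v = 2.0 * lo - v;
    else if (v > hi) v = 2.0 * hi - v;
    else return v;
  }
  return std::min(std::max(v, lo), hi);
}

// [[Rcpp::export]]
List run_steps_cpp(NumericVector px0, NumericVector py0,
                   LogicalVector occupied0, LogicalVector eligible0,
                   IntegerVector parent_area, IntegerVector target0,
                   NumericVector soma_x, NumericVector soma_y,
                   NumericMatrix area_bounds, NumericVector sheet_bounds,
                   double step_length, double contact_radius,
                   double accept_prob, int t_start, int n_steps) {
  const int n = px0.size();
  const int ns = soma_x.size();
  NumericVector px = clone(px0), py = clone(py0);
  LogicalVector occupied = clone(occupied0), eligible = clone(eligible0);
  IntegerVector target = clone(target0);

  const double xlo = sheet_bounds[0], xhi = sheet_bounds[1];
  const double ylo = sheet_bounds[2], yhi = sheet_bounds[3];
  const double r2 = contact_radius * contact_radius;

  // spatial bucketing of somata; cell size >= contact_radius so a disc query
  // touches at most a 3x3 block of cells
  double w = std::max(xhi - xlo, 1e-12), h = std::max(yhi - ylo, 1e-12);
  double cell = std::max(contact_radius,
                         std::sqrt(w * h / std::max(ns, 1)));
  int nx = std::max(1, (int)std::ceil(w / cell));
  int ny = std::max(1, (int)std::ceil(h / cell));
  std::vector<int> head((size_t)nx * ny, -1), nxt(ns, -1);
  for (int j = 0; j < ns; ++j) {
    int cx = std::min(nx - 1, std::max(0, (int)((soma_x[j] - xlo) / cell)));
    int cy = std::min(ny - 1, std::max(0, (int)((soma_y[j] - ylo) / cell)));
    int c = cy * nx + cx;
    nxt[j] = head[c];
    head[c] = j;
  }

  std::vector<int> syn_src, syn_tgt, syn_t;
  std::vector<int> cand;
  cand.reserve(64);
  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    const int t = t_start + s;
    // pass 1: extend
    for (int i = 0; i < n; ++i) {
      if (occupied[i]) continue;
      double ang = 2.0 * M_PI * unif_rand();
      double x = reflect1(px[i] + step_length * std::cos(ang), xlo, xhi);
      double y = reflect1(py[i] + step_length * std::sin(ang), ylo, yhi);
      px[i] = x;
      py[i] = y;
      if (!eligible[i]) {
        int a = parent_area[i] - 1;
        if (x < area_bounds(a, 0) || x > area_bounds(a, 1) ||
            y < area_bounds(a, 2) || y > area_bounds(a, 3))
          eligible[i] = true;
      }
    }
    // pass 2: attempt synapses
    for (int i = 0; i < n; ++i) {
      if (occupied[i] || !eligible[i]) continue;
      const double x = px[i], y = py[i];
      int cx0 = std::max(0, (int)((x - contact_radius - xlo) / cell));
      int cx1 = std::min(nx - 1, (int)((x + contact_radius - xlo) / cell));
      int cy0 = std::max(0, (int)((y - contact_radius - ylo) / cell));
      int cy1 = std::min(ny - 1, (int)((y + contact_radius - ylo) / cell));
      double best = r2;
      cand.clear();
      for (int cy = cy0; cy <= cy1; ++cy) {
        for (int cx = cx0; cx <= cx1; ++cx) {
          for (int j = head[cy * nx + cx]; j != -1; j = nxt[j]) {
            if (j == i) continue;  // own soma
            double dx = soma_x[j] - x, dy = soma_y[j] - y;
            double d2 = dx * dx + dy * dy;
            if (d2 < best) {
              best = d2;
              cand.clear();
              cand.push_back(j);
            } else if (d2 == best && d2 < r2) {
              cand.push_back(j);
            }
          }
        }
      }
      if (cand.empty()) continue;
      int j;
      if (cand.size() == 1) {
        j = cand[0];
      } else {
        std::sort(cand.begin(), cand.end());
        int k = (int)(unif_rand() * cand.size());
        if (k >= (int)cand.size()) k = (int)cand.size() - 1;
        j = cand[k];
      }
      if (unif_rand() < accept_prob) {
        occupied[i] = true;
        target[i] = j + 1;
        px[i] = soma_x[j];
        py[i] = soma_y[j];
        syn_src.push_back(i + 1);
        syn_tgt.push_back(j + 1);
        syn_t.push_back(t);
      }
    }
  }

  return List::create(
    _["px"] = px, _["py"] = py, _["occupied"] = occupied,
    _["eligible"] = eligible, _["target"] = target,
    _["syn_source"] = IntegerVector(syn_src.begin(), syn_src.end()),
    _["syn_target"] = IntegerVector(syn_tgt.begin(), syn_tgt.end()),
    _["syn_time"] = IntegerVector(syn_t.begin(), syn_t.end()));
}
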