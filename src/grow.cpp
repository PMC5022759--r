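#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Seeded region growing with a FIFO frontier and incrementally updated
// region statistics.
//
// neigh_code: 4 = axial 4-neighborhood, 5 = diagonal 4-neighborhood,
//             8 = full 8-neighborhood.
// var_method: 1 = Welford's numerically stable recurrence (default),
//             2 = the raw recurrence V_N = ((N-2) V_{N-1} + I_N) / N.
//
// A frontier pixel p is accepted iff |I_p - mu| <= max(k_sigma * sd, t_min),
// where mu/sd are the live region statistics (population sd) or, in frozen
// mode, the supplied constants. Each pixel is enqueued and tested at most
// once; neighbors are pushed in row-major order over the 3x3 window, so the
// traversal is fully deterministic.
// [[Rcpp::export]]
List grow_region_core(NumericMatrix img, int seed_row, int seed_col,
                      LogicalMatrix eligible, int neigh_code,
                      double k_sigma, double t_min,
                      bool frozen, double frozen_mean, double frozen_sd,
                      int var_method) {
  const int nr = img.nrow(), nc = img.ncol();
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> off;
  for (int k = 0; k < 8; ++k) {
    bool diag = dr8[k] != 0 && dc8[k] != 0;
    if (neigh_code == 8 || (neigh_code == 4 && !diag) ||
        (neigh_code == 5 && diag))
      off.push_back(k);
  }

  LogicalMatrix mask(nr, nc);
  std::vector<char> queued((size_t)nr * nc, 0);
  std::queue<long> q;

  const int sr = seed_row, sc = seed_col; // 0-based
  double n = 1.0, mean = img(sr, sc), m2 = 0.0, vprint = 0.0;
  mask(sr, sc) = true;
  queued[(size_t)sc * nr + sr] = 1;
  for (size_t k = 0; k < off.size(); ++k) {
    int r = sr + dr8[off[k]], c = sc + dc8[off[k]];
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (!eligible(r, c)) continue;
    size_t idx = (size_t)c * nr + r;
    if (!queued[idx]) { queued[idx] = 1; q.push((long)idx); }
  }

  while (!q.empty()) {
    long idx = q.front();
    q.pop();
    int r = (int)(idx % nr), c = (int)(idx / nr);
    double x = img(r, c);
    double mu, sd;
    if (frozen) {
      mu = frozen_mean;
      sd = frozen_sd;
    } else {
      mu = mean;
      sd = (var_method == 1) ? std::sqrt(m2 / n)
                             : std::sqrt(vprint > 0.0 ? vprint : 0.0);
    }
    double tol = std::max(k_sigma * sd, t_min);
    if (std::fabs(x - mu) > tol) continue;

    mask(r, c) = true;
    n += 1.0;
    if (var_method == 1) {
      double d = x - mean;
      mean += d / n;
      m2 += d * (x - mean);
    } else {
      mean = ((n - 1.0) * mean + x) / n;
      vprint = ((n - 2.0) * vprint + x) / n;
    }
    for (size_t k = 0; k < off.size(); ++k) {
      int r2 = r + dr8[off[k]], c2 = c + dc8[off[k]];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!eligible(r2, c2)) continue;
      size_t idx2 = (size_t)c2 * nr + r2;
      if (!queued[idx2]) { queued[idx2] = 1; q.push((long)idx2); }
    }
  }

  double disp = (var_method == 1) ? m2 : vprint;
  double sd_out = (var_method == 1) ? std::sqrt(m2 / n)
                                    : std::sqrt(vprint > 0.0 ? vprint : 0.0);
  return List::create(_["mask"] = mask, _["n"] = n, _["mean"] = mean,
                      _["disp"] = disp, _["sd"] = sd_out);
}
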