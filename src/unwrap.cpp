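#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided region-growing phase unwrapping on a 3-D grid.
//
// Voxels are visited in decreasing quality order starting from the
// highest-quality masked voxel; each new voxel's unwrapped value is the
// neighbour's value plus the wrapped difference of the raw phases, which
// keeps the output congruent with the input modulo 2*pi at every voxel.
// Disconnected mask components are unwrapped independently (each re-seeded),
// since inter-component offsets are indeterminate.

static inline double wrap_pi(double x) {
  const double TWO_PI = 2.0 * M_PI;
  // floor-based wrap (avoids fmod, which needs a newer libm than the runtime)
  double w = x + M_PI - TWO_PI * std::floor((x + M_PI) / TWO_PI) - M_PI;
  if (w == -M_PI) w = M_PI;
  return w;
}

// [[Rcpp::export(name = ".unwrapCpp")]]
List unwrapCpp(NumericVector wrapped, LogicalVector mask,
               NumericVector quality, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out = clone(wrapped);
  std::vector<char> state(n, 0);  // 0 unvisited, 1 queued, 2 done
  typedef std::pair<double, int> QI;
  std::priority_queue<QI> pq;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  int ncomp = 0;
  int remaining = 0;
  for (int i = 0; i < n; ++i) if (mask[i]) ++remaining;

  while (remaining > 0) {
    // seed: highest-quality unvisited masked voxel
    int seed = -1; double best = -1e300;
    for (int i = 0; i < n; ++i)
      if (mask[i] && state[i] == 0 && quality[i] > best) { best = quality[i]; seed = i; }
    if (seed < 0) break;
    ++ncomp;
    state[seed] = 1;
    pq.push(QI(quality[seed], seed));
    while (!pq.empty()) {
      int cur = pq.top().second; pq.pop();
      if (state[cur] == 2) continue;
      state[cur] = 2; --remaining;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int k = 0; k < 6; ++k) {
        int xx = cx + dx[k], yy = cy + dy[k], zz = cz + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int nb = xx + nx * (yy + ny * zz);
        if (!mask[nb] || state[nb] != 0) continue;
        out[nb] = out[cur] + wrap_pi(wrapped[nb] - wrapped[cur]);
        state[nb] = 1;
        pq.push(QI(quality[nb], nb));
      }
    }
  }
  return List::create(_["unwrapped"] = out, _["ncomponents"] = ncomp);
}
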