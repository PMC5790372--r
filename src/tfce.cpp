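#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int uf_find(std::vector<int> &parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];  // path halving
    v = parent[v];
  }
  return v;
}

// Threshold-free cluster enhancement on a masked lattice with a precomputed
// adjacency list. values must be >= 0 (the R wrapper splits signs).
// nbr: 0-based neighbour indices, CSR layout with offsets ptr (length n + 1).
// enh[v] = sum over thresholds h = dh, 2dh, ..., of e_v(h)^E * h^H * dh,
// where e_v(h) is the size of the connected suprathreshold component
// containing v. Voxels are activated in decreasing value order and merged
// with union-find, so each threshold pass is near-linear in active voxels.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerVector nbr, IntegerVector ptr,
                       double E, double H, double dh) {
  const int n = values.size();
  NumericVector enh(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0 || dh <= 0.0) return enh;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(n, -1), sz(n, 0), stamp(n, -1);
  std::vector<char> active(n, 0);
  std::vector<double> rootval(n, 0.0);

  const int nsteps = (int) std::floor(vmax / dh + 1e-12);
  int next = 0;
  for (int step = nsteps; step >= 1; --step) {
    const double h = step * dh;
    while (next < n && values[ord[next]] >= h) {
      const int v = ord[next++];
      active[v] = 1; parent[v] = v; sz[v] = 1;
      for (int j = ptr[v]; j < ptr[v + 1]; ++j) {
        const int u = nbr[j];
        if (!active[u]) continue;
        const int rv = uf_find(parent, v), ru = uf_find(parent, u);
        if (rv != ru) {
          if (sz[rv] >= sz[ru]) { parent[ru] = rv; sz[rv] += sz[ru]; }
          else                  { parent[rv] = ru; sz[ru] += sz[rv]; }
        }
      }
    }
    const double hterm = std::pow(h, H) * dh;
    for (int k = 0; k < next; ++k) {
      const int v = ord[k];
      const int r = uf_find(parent, v);
      if (stamp[r] != step) {
        rootval[r] = std::pow((double) sz[r], E) * hterm;
        stamp[r] = step;
      }
      enh[v] += rootval[r];
    }
  }
  return enh;
}
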