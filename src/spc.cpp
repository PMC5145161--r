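// Superparamagnetic clustering: Potts model on a nearest-neighbour
// interaction graph, simulated with the Swendsen-Wang cluster
// algorithm over a sweep of temperatures. Clusters are read out as
// connected components of point pairs whose spin-spin correlation
// exceeds a threshold.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Self-contained 64-bit RNG (splitmix64 seeding + xoshiro256**-like
// core) so results are bit-identical regardless of R's RNG state,
// compiler stdlib, or worker scheduling.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int integer(int m) { return (int)(next() % (uint64_t)m); }
};

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  void reset() {
    for (size_t i = 0; i < parent.size(); ++i) parent[i] = (int)i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

static double dist2(const double *X, int n, int d, int i, int j) {
  double acc = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = X[i + (size_t)n * c] - X[j + (size_t)n * c];
    acc += diff * diff;
  }
  return acc;
}

// Relabel component ids as 1..C by decreasing component size (ties:
// first appearance in point order).
static void relabel_by_size(std::vector<int> &lab) {
  int n = (int)lab.size();
  std::vector<int> count;
  std::vector<int> first;
  std::vector<int> id(n, -1);
  int c = 0;
  for (int i = 0; i < n; ++i) {
    if (id[lab[i]] < 0) {
      id[lab[i]] = c++;
      count.push_back(0);
      first.push_back(i);
    }
    count[id[lab[i]]]++;
  }
  std::vector<int> ord(c);
  for (int i = 0; i < c; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (count[a] != count[b]) return count[a] > count[b];
    return first[a] < first[b];
  });
  std::vector<int> newid(c);
  for (int r = 0; r < c; ++r) newid[ord[r]] = r + 1;
  for (int i = 0; i < n; ++i) lab[i] = newid[id[lab[i]]];
}

// [[Rcpp::export(name = ".spc_sw_cpp")]]
IntegerMatrix spc_sw_cpp(NumericMatrix X, NumericVector temps, int q,
                         int knn, int sweeps, int burnin,
                         double corr_thresh, double seed,
                         bool complete_graph) {
  const int n = X.nrow(), d = X.ncol();
  const double *xp = X.begin();
  const int nT = temps.size();

  // --- interaction graph: union of kNN links and the MST -----------
  std::vector<std::pair<int, int> > edges;
  double a_sum = 0.0;
  long a_cnt = 0;
  if (complete_graph || n <= knn + 1) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        edges.push_back(std::make_pair(i, j));
        a_sum += std::sqrt(dist2(xp, n, d, i, j));
        ++a_cnt;
      }
  } else {
    std::vector<double> dist_i(n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) dist_i[j] = dist2(xp, n, d, i, j);
      dist_i[i] = R_PosInf;
      for (int j = 0; j < n; ++j) idx[j] = j;
      std::partial_sort(idx.begin(), idx.begin() + knn, idx.end(),
                        [&](int a, int b) {
                          return dist_i[a] < dist_i[b];
                        });
      for (int r = 0; r < knn; ++r) {
        int j = idx[r];
        a_sum += std::sqrt(dist_i[j]);
        ++a_cnt;
        edges.push_back(std::make_pair(std::min(i, j),
                                       std::max(i, j)));
      }
    }
    // Prim's MST keeps the graph connected so that the zero-
    // temperature limit is a single cluster.
    std::vector<double> best(n, R_PosInf);
    std::vector<int> from(n, -1);
    std::vector<bool> used(n, false);
    best[0] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double bu = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!used[v] && best[v] < bu) { bu = best[v]; u = v; }
      used[u] = true;
      if (from[u] >= 0)
        edges.push_back(std::make_pair(std::min(u, from[u]),
                                       std::max(u, from[u])));
      for (int v = 0; v < n; ++v) {
        if (used[v]) continue;
        double dv = dist2(xp, n, d, u, v);
        if (dv < best[v]) { best[v] = dv; from[v] = u; }
      }
    }
    std::sort(edges.begin(), edges.end());
    edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  }
  const int ne = (int)edges.size();
  const double a = a_cnt ? a_sum / a_cnt : 1.0;
  // normalize by the mutual-neighbour mean degree (about half the
  // union-graph degree); this places the superparamagnetic window of
  // typical spike data inside the sweep's [0, 0.2] operating range
  const double khat = n ? 2.0 * ne / n : 1.0;

  std::vector<double> J(ne);
  for (int e = 0; e < ne; ++e) {
    double d2 = dist2(xp, n, d, edges[e].first, edges[e].second);
    J[e] = std::exp(-d2 / (2.0 * a * a)) / khat;
  }

  IntegerMatrix labels(nT, n);
  Rng rng((uint64_t)(int64_t)seed);
  std::vector<int> spin(n), comp_spin(n), lab(n), corr(ne);
  std::vector<double> pfreeze(ne);
  DSU dsu(n);

  for (int ti = 0; ti < nT; ++ti) {
    double T = temps[ti];
    if (T <= 0.0) {
      // ferromagnetic limit: every bond frozen, clusters = graph
      // components (a single one, by the MST union)
      dsu.reset();
      for (int e = 0; e < ne; ++e)
        dsu.unite(edges[e].first, edges[e].second);
      for (int i = 0; i < n; ++i) lab[i] = dsu.find(i);
      relabel_by_size(lab);
      for (int i = 0; i < n; ++i) labels(ti, i) = lab[i];
      continue;
    }
    for (int e = 0; e < ne; ++e)
      pfreeze[e] = 1.0 - std::exp(-J[e] / T);
    for (int i = 0; i < n; ++i) spin[i] = rng.integer(q);
    std::fill(corr.begin(), corr.end(), 0);
    const int total = burnin + sweeps;
    for (int sw = 0; sw < total; ++sw) {
      dsu.reset();
      for (int e = 0; e < ne; ++e)
        if (spin[edges[e].first] == spin[edges[e].second] &&
            rng.unif() < pfreeze[e])
          dsu.unite(edges[e].first, edges[e].second);
      for (int i = 0; i < n; ++i) comp_spin[i] = -1;
      for (int i = 0; i < n; ++i) {
        int r = dsu.find(i);
        if (comp_spin[r] < 0) comp_spin[r] = rng.integer(q);
        spin[i] = comp_spin[r];
      }
      if (sw >= burnin)
        for (int e = 0; e < ne; ++e)
          if (spin[edges[e].first] == spin[edges[e].second]) ++corr[e];
    }
    // two-point spin correlation G in [0, 1]; link pairs above the
    // threshold, then capture every point into the cluster of its
    // maximally correlated neighbour (the standard SPC cluster
    // construction), and read clusters as connected components
    dsu.reset();
    for (int e = 0; e < ne; ++e) {
      double c = (double)corr[e] / sweeps;
      double g = (q * c - 1.0) / (q - 1.0);
      if (g > corr_thresh)
        dsu.unite(edges[e].first, edges[e].second);
    }
    {
      // core clusters from the threshold are left intact; points the
      // threshold leaves on their own are captured towards their
      // maximally correlated neighbour (chains of captured points
      // coalesce, so melted regions break into landscape basins
      // rather than single points)
      std::vector<int> comp_size(n, 0);
      for (int i = 0; i < n; ++i) comp_size[dsu.find(i)]++;
      std::vector<int> best_cnt(n, -1), best_nb(n, -1);
      for (int e = 0; e < ne; ++e) {
        int u = edges[e].first, v = edges[e].second;
        if (corr[e] > best_cnt[u] ||
            (corr[e] == best_cnt[u] && v < best_nb[u])) {
          best_cnt[u] = corr[e];
          best_nb[u] = v;
        }
        if (corr[e] > best_cnt[v] ||
            (corr[e] == best_cnt[v] && u < best_nb[v])) {
          best_cnt[v] = corr[e];
          best_nb[v] = u;
        }
      }
      for (int i = 0; i < n; ++i)
        if (best_nb[i] >= 0 && comp_size[dsu.find(i)] == 1)
          dsu.unite(best_nb[i], i);
    }
    for (int i = 0; i < n; ++i) lab[i] = dsu.find(i);
    relabel_by_size(lab);
    for (int i = 0; i < n; ++i) labels(ti, i) = lab[i];
    Rcpp::checkUserInterrupt();
  }
  return labels;
}
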