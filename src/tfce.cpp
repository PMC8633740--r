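// Threshold-free cluster enhancement and the sign-flip permutation kernels.
// TFCE sweeps thresholds from high to low with an incremental union-find:
// voxels enter as the threshold drops below their value, merge with present
// neighbours, and every present voxel accumulates e(h)^E * h^H * dh at each
// step. The permutation engines recompute the one-sample t map and the TFCE
// maximum per sign flip; these loops dominate the cost of the null
// calibrations, hence C++.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent;
  std::vector<double> size;
  explicit UnionFind(int n) : parent(n, -1), size(n, 0.0) {}
  int find(int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) { int nx = parent[x]; parent[x] = root; x = nx; }
    return root;
  }
  void add(int x) { parent[x] = x; size[x] = 1.0; }
  bool present(int x) const { return parent[x] >= 0; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Union-find that also carries, per node, the enhancement "shift" relative
// to its parent, so cluster-wide increments can be accumulated lazily at
// roots (acc) instead of per member per threshold step. The true total of a
// node is acc[root] + sum of shifts along its (compressed) path.
struct TfceForest {
  std::vector<int> parent;
  std::vector<double> size, acc, shift;
  std::vector<int> roots;     // live roots (lazily pruned)
  void reset(int n) {
    parent.assign(n, -1);
    size.assign(n, 0.0);
    acc.assign(n, 0.0);
    shift.assign(n, 0.0);
    roots.clear();
  }
  bool present(int x) const { return parent[x] >= 0; }
  void add(int x) {
    parent[x] = x; size[x] = 1.0; acc[x] = 0.0; shift[x] = 0.0;
    roots.push_back(x);
  }
  // find with full path compression, folding shifts into the compressed edge
  int find(int x) {
    if (parent[x] == x) return x;
    int root = x;
    double sum = 0.0;
    while (parent[root] != root) { sum += shift[root]; root = parent[root]; }
    // second pass: repoint everything at the root with cumulated shift
    int cur = x;
    double above = sum;              // shift sum from cur (exclusive) to root
    while (parent[cur] != root) {
      int nxt = parent[cur];
      double s = shift[cur];
      shift[cur] = above;            // now relative to root
      above -= s;
      parent[cur] = root;
      cur = nxt;
    }
    return root;
  }
  double value(int x) {
    int r = find(x);
    return acc[r] + (x == r ? 0.0 : shift[x]);
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    shift[b] = acc[b] - acc[a];
    size[a] += size[b];
  }
};

// neighbour offsets for 6/18/26 connectivity on a dx x dy x dz grid
void neighbour_offsets(int conn, std::vector<std::array<int,3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (conn == 6 && nz > 1) continue;
        if (conn == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// TFCE of the positive part of `stat` (length nvox, flattened 3D). dh <= 0
// means max(stat)/nsteps. Thresholds are swept from high to low; voxels
// enter an incremental union-find and cluster-wide increments accumulate
// lazily at the roots (see TfceForest), so the cost per step is the number
// of live clusters, not the number of suprathreshold voxels.
void tfce_pos(const double* stat, int dx, int dy, int dz, double E, double H,
              double dh, int conn, int nsteps, double* out,
              TfceForest& uf) {
  const int nvox = dx * dy * dz;
  std::fill(out, out + nvox, 0.0);
  double mx = 0.0;
  for (int i = 0; i < nvox; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0) return;
  if (dh <= 0.0) dh = mx / nsteps;
  std::vector<int> order;
  order.reserve(256);
  for (int i = 0; i < nvox; ++i) if (stat[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [stat](int a, int b) { return stat[a] > stat[b]; });
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(conn, offs);
  uf.reset(nvox);
  size_t next = 0;
  int top = (int)std::floor(mx / dh + 1e-12);
  for (int step = top; step >= 1; --step) {
    double h = step * dh;
    while (next < order.size() && stat[order[next]] >= h) {
      int v = order[next++];
      uf.add(v);
      int z = v / (dx * dy), rem = v % (dx * dy);
      int y = rem / dx, x = rem % dx;
      for (const auto& o : offs) {
        int nx2 = x + o[0], ny2 = y + o[1], nz2 = z + o[2];
        if (nx2 < 0 || nx2 >= dx || ny2 < 0 || ny2 >= dy || nz2 < 0 || nz2 >= dz)
          continue;
        int u = nx2 + dx * (ny2 + dy * nz2);
        if (uf.present(u)) uf.unite(v, u);
      }
    }
    // lazily prune dead roots, then credit each live cluster once
    double hh = std::pow(h, H) * dh;
    size_t w = 0;
    for (size_t i = 0; i < uf.roots.size(); ++i) {
      int r = uf.roots[i];
      if (uf.parent[r] != r) continue;
      uf.roots[w++] = r;
      uf.acc[r] += std::pow(uf.size[r], E) * hh;
    }
    uf.roots.resize(w);
  }
  // voxels with 0 < stat < dh were never added (no threshold below them)
  for (int v : order) if (uf.present(v)) out[v] = uf.value(v);
}

// one-sample t over rows of diffs (n x v, column-major) with signs applied
void signed_t(const double* diffs, int n, int v, const int* signs,
              double* tmap) {
  for (int j = 0; j < v; ++j) {
    const double* col = diffs + (size_t)j * n;
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = signs[i] * col[i];
      s += x;
      ss += x * x;
    }
    double mean = s / n;
    double var = (ss - n * mean * mean) / (n - 1);
    tmap[j] = (var > 0.0) ? mean / std::sqrt(var / n) : 0.0;
  }
}

} // namespace

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh, int conn, int nsteps) {
  if (dims.size() != 3) stop("dims must have length 3");
  int dx = dims[0], dy = dims[1], dz = dims[2];
  if ((size_t)stat.size() != (size_t)dx * dy * dz)
    stop("stat length does not match dims");
  NumericVector out(stat.size());
  TfceForest uf;
  tfce_pos(REAL(stat), dx, dy, dz, E, H, dh, conn, nsteps, REAL(out), uf);
  return out;
}

// Sign-flip permutation engine for voxelwise TFCE inference.
// diffs: n x v matrix of subject difference images (v = prod(dims), mask
// already applied by zeroing outside voxels is NOT assumed: pass full grid
// with zeros outside the mask). signs: nperm x n matrix of +/-1; row 0 is
// ignored for the null (the observed statistic itself is the identity
// permutation). Returns observed t, tfce+ and tfce- maps plus the null
// distributions of the max TFCE per direction.
// [[Rcpp::export(name = ".tfce_perm_cpp")]]
List tfce_perm_cpp(NumericMatrix diffs, IntegerVector dims, double E,
                   double H, int conn, int nsteps, IntegerMatrix signs) {
  int n = diffs.nrow();
  int v = diffs.ncol();
  int dx = dims[0], dy = dims[1], dz = dims[2];
  if ((size_t)v != (size_t)dx * dy * dz) stop("diffs/dims mismatch");
  if (signs.ncol() != n) stop("signs must be nperm x n");
  int nperm = signs.nrow();
  std::vector<double> tmap(v), neg(v), enh(v);
  TfceForest uf2;
  std::vector<int> svec(n);
  NumericVector obs_t(v), obs_pos(v), obs_neg(v);
  NumericVector max_pos(nperm), max_neg(nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) svec[i] = signs(p, i);
    signed_t(REAL(diffs), n, v, svec.data(), tmap.data());
    tfce_pos(tmap.data(), dx, dy, dz, E, H, -1.0, conn, nsteps, enh.data(), uf2);
    double mp = 0.0;
    for (int j = 0; j < v; ++j) if (enh[j] > mp) mp = enh[j];
    if (p == 0) std::copy(enh.begin(), enh.end(), obs_pos.begin());
    max_pos[p] = mp;
    for (int j = 0; j < v; ++j) neg[j] = -tmap[j];
    tfce_pos(neg.data(), dx, dy, dz, E, H, -1.0, conn, nsteps, enh.data(), uf2);
    double mn = 0.0;
    for (int j = 0; j < v; ++j) if (enh[j] > mn) mn = enh[j];
    if (p == 0) {
      std::copy(enh.begin(), enh.end(), obs_neg.begin());
      std::copy(tmap.begin(), tmap.end(), obs_t.begin());
    }
    max_neg[p] = mn;
  }
  return List::create(_["t"] = obs_t, _["tfce_pos"] = obs_pos,
                      _["tfce_neg"] = obs_neg, _["max_pos"] = max_pos,
                      _["max_neg"] = max_neg);
}

// Sign-flip permutation engine for NBS (network-based statistic).
// diffs: n x e matrix of per-subject edge differences (e = K*(K-1)/2 in
// upper-triangle column order), edge_i/edge_j: 0-based network indices per
// edge, tcrit: edge-inclusion |t| threshold, signs as above (row 0 =
// identity/observed). Component statistic = sum of |t| over edges (mass).
// Returns observed t per edge and the null max component mass per direction.
// [[Rcpp::export(name = ".nbs_perm_cpp")]]
List nbs_perm_cpp(NumericMatrix diffs, IntegerVector edge_i,
                  IntegerVector edge_j, int K, double tcrit,
                  IntegerMatrix signs, int stat_type) {
  int n = diffs.nrow();
  int e = diffs.ncol();
  int nperm = signs.nrow();
  std::vector<double> tmap(e);
  std::vector<int> svec(n);
  NumericVector obs_t(e);
  NumericVector max_pos(nperm), max_neg(nperm);
  UnionFind uf(K);
  std::vector<double> mass(K);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) svec[i] = signs(p, i);
    signed_t(REAL(diffs), n, e, svec.data(), tmap.data());
    if (p == 0) std::copy(tmap.begin(), tmap.end(), obs_t.begin());
    for (int dir = 0; dir < 2; ++dir) {
      uf.parent.assign(K, -1);
      uf.size.assign(K, 0.0);
      std::fill(mass.begin(), mass.end(), 0.0);
      // build suprathreshold graph over networks, accumulate mass at roots
      for (int k = 0; k < K; ++k) uf.add(k);
      for (int q = 0; q < e; ++q) {
        double t = dir == 0 ? tmap[q] : -tmap[q];
        if (t > tcrit) uf.unite(edge_i[q], edge_j[q]);
      }
      for (int q = 0; q < e; ++q) {
        double t = dir == 0 ? tmap[q] : -tmap[q];
        if (t > tcrit)
          mass[uf.find(edge_i[q])] += stat_type == 0 ? std::fabs(tmap[q]) : 1.0;
      }
      double mx = 0.0;
      for (int k = 0; k < K; ++k) if (mass[k] > mx) mx = mass[k];
      if (dir == 0) max_pos[p] = mx; else max_neg[p] = mx;
    }
  }
  return List::create(_["t"] = obs_t, _["max_pos"] = max_pos,
                      _["max_neg"] = max_neg);
}
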