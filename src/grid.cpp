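#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Column-major linear index for a nx*ny*nz grid.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Mark grid cells whose center lies within radii[a] of atom a.
// Cell (i,j,k) center = origin + (i+0.5, j+0.5, k+0.5) * h.
// [[Rcpp::export]]
LogicalVector cpp_occupancy(NumericMatrix coords, NumericVector radii,
                            NumericVector origin, IntegerVector dims,
                            double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    const double r = radii[a], r2 = r * r;
    // cell index range possibly touched by this atom
    int i0 = (int)std::floor((x - r - origin[0]) / h - 0.5);
    int i1 = (int)std::ceil((x + r - origin[0]) / h - 0.5);
    int j0 = (int)std::floor((y - r - origin[1]) / h - 0.5);
    int j1 = (int)std::ceil((y + r - origin[1]) / h - 0.5);
    int k0 = (int)std::floor((z - r - origin[2]) / h - 0.5);
    int k1 = (int)std::ceil((z + r - origin[2]) / h - 0.5);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + (k + 0.5) * h - z;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + (j + 0.5) * h - y;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + (i + 0.5) * h - x;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[lin(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      s = ((f[i] + i * (double)i) - (f[v[q]] + v[q] * (double)v[q])) /
          (2.0 * i - 2.0 * v[q]);
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = std::numeric_limits<double>::infinity();
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    const double di = i - (double)v[q];
    d[i] = di * di + f[v[q]];
  }
}

// Squared Euclidean distance (in Angstrom^2) from every cell center to the
// nearest TRUE cell center. Cells are unit h apart along each axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: +inf would produce inf-inf = NaN in the
  // parabola-intersection step
  const double BIG = 1e20;
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (R_xlen_t t = 0; t < out.size(); ++t) out[t] = mask[t] ? 0.0 : BIG;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) out[lin(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = d[k];
    }
  const double h2 = h * h;
  for (R_xlen_t t = 0; t < out.size(); ++t) out[t] *= h2;
  return out;
}

// 6-connected component labels over TRUE cells; 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_components6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<R_xlen_t> bfs;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = lin(i, j, k, nx, ny);
        if (!mask[t] || lab[t]) continue;
        lab[t] = ++next;
        bfs.push(t);
        while (!bfs.empty()) {
          R_xlen_t c = bfs.front(); bfs.pop();
          int ci = (int)(c % nx);
          int cj = (int)((c / nx) % ny);
          int ck = (int)(c / ((R_xlen_t)nx * ny));
          for (int s = 0; s < 6; ++s) {
            int ii = ci + di[s], jj = cj + dj[s], kk = ck + dk[s];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t u = lin(ii, jj, kk, nx, ny);
            if (mask[u] && !lab[u]) { lab[u] = next; bfs.push(u); }
          }
        }
      }
  return lab;
}

static inline long long cellkey(int i, int j, int k) {
  // cells live well inside +/- 2^20 of the origin
  const long long B = 1 << 21, H = 1 << 20;
  return ((long long)(i + H)) + B * ((long long)(j + H) + B * (long long)(k + H));
}

// Number of exposed 6-neighbour faces of a cell set (rows = integer triples).
// [[Rcpp::export]]
int cpp_exposed_faces(IntegerMatrix cells) {
  std::unordered_set<long long> set;
  set.reserve(cells.nrow() * 2);
  for (int r = 0; r < cells.nrow(); ++r)
    set.insert(cellkey(cells(r, 0), cells(r, 1), cells(r, 2)));
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  int faces = 0;
  for (int r = 0; r < cells.nrow(); ++r)
    for (int s = 0; s < 6; ++s)
      if (!set.count(cellkey(cells(r, 0) + di[s], cells(r, 1) + dj[s],
                             cells(r, 2) + dk[s])))
        ++faces;
  return faces;
}

// Minimum distance from each query point to any of a set of points.
// Used for pocket-lining tests (cell centers vs. atom coordinates).
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix query, NumericMatrix ref) {
  NumericVector out(query.nrow());
  for (int a = 0; a < query.nrow(); ++a) {
    double best = std::numeric_limits<double>::infinity();
    for (int b = 0; b < ref.nrow(); ++b) {
      const double dx = query(a, 0) - ref(b, 0);
      const double dy = query(a, 1) - ref(b, 1);
      const double dz = query(a, 2) - ref(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// All atom pairs closer than cutoff, via a uniform cell hash.
// Returns i, j (1-based) and the distance.
// [[Rcpp::export]]
List cpp_close_pairs(NumericMatrix coords, double cutoff) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  auto ckey = [](int i, int j, int k) {
    const long long B = 1 << 21, H = 1 << 20;
    return ((long long)(i + H)) + B * ((long long)(j + H) + B * (long long)(k + H));
  };
  for (int a = 0; a < n; ++a) {
    int i = (int)std::floor(coords(a, 0) / cutoff);
    int j = (int)std::floor(coords(a, 1) / cutoff);
    int k = (int)std::floor(coords(a, 2) / cutoff);
    key[a] = ckey(i, j, k);
    cells[key[a]].push_back(a);
  }
  std::vector<int> ri, rj;
  std::vector<double> rd;
  for (int a = 0; a < n; ++a) {
    int ci = (int)std::floor(coords(a, 0) / cutoff);
    int cj = (int)std::floor(coords(a, 1) / cutoff);
    int ck = (int)std::floor(coords(a, 2) / cutoff);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          auto it = cells.find(ckey(ci + di, cj + dj, ck + dk));
          if (it == cells.end()) continue;
          for (int b : it->second) {
            if (b <= a) continue;
            const double dx = coords(a, 0) - coords(b, 0);
            const double dy = coords(a, 1) - coords(b, 1);
            const double dz = coords(a, 2) - coords(b, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < c2) {
              ri.push_back(a + 1);
              rj.push_back(b + 1);
              rd.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return List::create(Named("i") = wrap(ri), Named("j") = wrap(rj),
                      Named("d") = wrap(rd));
}

// Minimum heavy-atom distance per residue pair, for residue pairs whose
// closest atoms are within cutoff. res is a 1-based residue id per atom.
// Returns res_i, res_j (i < j) and the minimum distance.
// [[Rcpp::export]]
List cpp_res_min_dist(NumericMatrix coords, IntegerVector res, double cutoff) {
  List cp = cpp_close_pairs(coords, cutoff);
  IntegerVector pi = cp["i"], pj = cp["j"];
  NumericVector pd = cp["d"];
  std::unordered_map<long long, double> best;
  for (R_xlen_t t = 0; t < pi.size(); ++t) {
    int ra = res[pi[t] - 1], rb = res[pj[t] - 1];
    if (ra == rb) continue;
    if (ra > rb) std::swap(ra, rb);
    long long k = (long long)ra * 1000000LL + rb;
    auto it = best.find(k);
    if (it == best.end() || pd[t] < it->second) best[k] = pd[t];
  }
  std::vector<int> oi, oj;
  std::vector<double> od;
  for (auto &kv : best) {
    oi.push_back((int)(kv.first / 1000000LL));
    oj.push_back((int)(kv.first % 1000000LL));
    od.push_back(kv.second);
  }
  return List::create(Named("res_i") = wrap(oi), Named("res_j") = wrap(oj),
                      Named("d") = wrap(od));
}
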