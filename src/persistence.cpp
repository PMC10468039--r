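// Vietoris-Rips persistent homology over Z/2 from a dense distance matrix.
//
// dim 0: union-find over edges in filtration order (deaths = MST edge
//        weights, the single-linkage merge heights).
// dims 1-2: cohomology-side reduction of the anti-transposed boundary matrix
//        with clearing, the strategy that makes VR persistence tractable:
//        columns are d-simplices processed in decreasing filtration order,
//        each holding its (d+1)-cofacets; the pivot is the cofacet earliest
//        in the filtration. Clearing skips columns known to be negative from
//        the dimension below (MST edges for d = 1; edge-paired triangles for
//        d = 2), so only the ~C(n,2) positive edge columns are ever reduced
//        instead of the ~C(n,3) triangle columns of the homology-side
//        algorithm. The pairing equals the standard boundary-matrix
//        reduction pairing (anti-transpose equivalence), which the test
//        suite verifies against a naive reduction oracle.
//
// Simplex order within a dimension: (filtration value, lexicographic vertex
// tuple), deterministic. Zero-persistence pairs are dropped at source.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// a (d+1)-cofacet entry in a coboundary column, ordered by original
// filtration order (value, lexicographic vertices)
struct CoKey {
  double v;
  int64_t id;  // lexicographic packing of the sorted vertex tuple
};

inline bool cokey_less(const CoKey &x, const CoKey &y) {
  if (x.v != y.v) return x.v < y.v;
  return x.id < y.id;
}

inline bool cokey_eq(const CoKey &x, const CoKey &y) {
  return x.v == y.v && x.id == y.id;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return false;
    parent[std::max(ra, rb)] = std::min(ra, rb);
    return true;
  }
};

// symmetric difference of two CoKey vectors sorted by cokey_less
inline void sym_diff(std::vector<CoKey> &col, const std::vector<CoKey> &other,
                     std::vector<CoKey> &tmp) {
  tmp.clear();
  std::set_symmetric_difference(col.begin(), col.end(), other.begin(),
                                other.end(), std::back_inserter(tmp),
                                cokey_less);
  col.swap(tmp);
}

inline double choose2(double n) { return n * (n - 1) / 2.0; }
inline double choose3(double n) { return n * (n - 1) * (n - 2) / 6.0; }
inline double choose4(double n) { return n * (n - 1) * (n - 2) * (n - 3) / 24.0; }

NumericMatrix bars_matrix(std::vector<double> &birth,
                          std::vector<double> &death) {
  // sort bars by (birth, death) for reproducible output
  const int k = (int)birth.size();
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (birth[x] != birth[y]) return birth[x] < birth[y];
    return death[x] < death[y];
  });
  NumericMatrix out(k, 2);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = birth[ord[i]];
    out(i, 1) = death[ord[i]];
  }
  colnames(out) = CharacterVector::create("birth", "death");
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".vr_persistence_cpp")]]
List vr_persistence_cpp(NumericMatrix D, int maxdim, double budget) {
  const int n = D.nrow();
  if (n < 1) stop("distance matrix must contain at least one point");
  if (D.ncol() != n) stop("distance matrix must be square");
  if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1 or 2");

  double nsimp = choose2((double)n);
  if (maxdim >= 1) nsimp += choose3((double)n);
  if (maxdim >= 2) nsimp += choose4((double)n);
  if (nsimp > budget)
    stop("simplex budget exceeded (%.3g simplices > budget %.3g): reduce the "
         "number of landmarks or lower maxdim",
         nsimp, budget);

  const int64_t N = n;
  const int m = n * (n - 1) / 2;

  // ---- edges sorted by (value, i, j) ------------------------------------
  struct Edge {
    double v;
    int a, b;
  };
  std::vector<Edge> edges;
  edges.reserve(m);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) edges.push_back(Edge{D(i, j), i, j});
  std::stable_sort(edges.begin(), edges.end(), [](const Edge &x, const Edge &y) {
    if (x.v != y.v) return x.v < y.v;
    if (x.a != y.a) return x.a < y.a;
    return x.b < y.b;
  });

  // ---- dimension 0: union-find ------------------------------------------
  std::vector<double> b0, d0;
  std::vector<char> is_mst(m, 0);
  {
    UnionFind uf(n);
    for (int r = 0; r < m; ++r) {
      if (uf.unite(edges[r].a, edges[r].b)) {
        is_mst[r] = 1;
        if (edges[r].v > 0.0) {
          b0.push_back(0.0);
          d0.push_back(edges[r].v);
        }
      }
    }
    b0.push_back(0.0);
    d0.push_back(R_PosInf);  // essential class of the connected endpoint
  }

  List out(maxdim + 1);
  out[0] = bars_matrix(b0, d0);
  if (maxdim == 0) return out;

  // ---- dimension 1: coboundary reduction of positive edge columns -------
  std::vector<double> b1, d1;
  // negative triangles (paired with an edge), as packed ids: cleared in dim 2
  std::unordered_map<int64_t, char> tri_negative;
  if (n >= 3) {
    // pivot triangle id -> index into stored reduced columns
    std::unordered_map<int64_t, int> pivot_owner;
    pivot_owner.reserve(m * 2);
    std::vector<std::vector<CoKey>> stored;
    std::vector<CoKey> col, tmp;
    for (int r = m - 1; r >= 0; --r) {  // decreasing filtration order
      if (is_mst[r]) continue;          // clearing: negative in dim 0
      const int a = edges[r].a, b = edges[r].b;
      const double fe = edges[r].v;
      col.clear();
      for (int v = 0; v < n; ++v) {
        if (v == a || v == b) continue;
        double val = fe;
        if (D(v, a) > val) val = D(v, a);
        if (D(v, b) > val) val = D(v, b);
        int x = a, y = b, z = v;
        if (z < y) std::swap(y, z);
        if (y < x) std::swap(x, y);
        if (z < y) std::swap(y, z);
        col.push_back(CoKey{val, ((int64_t)x * N + y) * N + z});
      }
      std::sort(col.begin(), col.end(), cokey_less);
      for (;;) {
        if (col.empty()) {
          // positive edge never paired: essential 1-cycle
          b1.push_back(fe);
          d1.push_back(R_PosInf);
          break;
        }
        const CoKey piv = col.front();  // earliest cofacet in filtration
        auto it = pivot_owner.find(piv.id);
        if (it == pivot_owner.end()) {
          pivot_owner.emplace(piv.id, (int)stored.size());
          stored.push_back(col);
          tri_negative[piv.id] = 1;
          if (piv.v > fe) {
            b1.push_back(fe);
            d1.push_back(piv.v);
          }
          break;
        }
        sym_diff(col, stored[it->second], tmp);
      }
    }
  }
  out[1] = bars_matrix(b1, d1);
  if (maxdim == 1) return out;

  // ---- dimension 2: coboundary reduction of positive triangle columns ---
  std::vector<double> b2, d2;
  if (n >= 4) {
    struct Tri {
      double v;
      int a, b, c;
    };
    std::vector<Tri> tris;
    tris.reserve((size_t)choose3((double)n));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double dij = D(i, j);
        for (int k = j + 1; k < n; ++k) {
          const int64_t id = ((int64_t)i * N + j) * N + k;
          if (tri_negative.count(id)) continue;  // clearing from dim 1
          double val = dij;
          if (D(i, k) > val) val = D(i, k);
          if (D(j, k) > val) val = D(j, k);
          tris.push_back(Tri{val, i, j, k});
        }
      }
    std::stable_sort(tris.begin(), tris.end(), [](const Tri &x, const Tri &y) {
      // decreasing filtration order for processing
      if (x.v != y.v) return x.v > y.v;
      if (x.a != y.a) return x.a > y.a;
      if (x.b != y.b) return x.b > y.b;
      return x.c > y.c;
    });
    std::unordered_map<int64_t, int> pivot_owner;
    std::vector<std::vector<CoKey>> stored;
    std::vector<CoKey> col, tmp;
    for (const Tri &t : tris) {
      col.clear();
      for (int v = 0; v < n; ++v) {
        if (v == t.a || v == t.b || v == t.c) continue;
        double val = t.v;
        if (D(v, t.a) > val) val = D(v, t.a);
        if (D(v, t.b) > val) val = D(v, t.b);
        if (D(v, t.c) > val) val = D(v, t.c);
        int q[4] = {t.a, t.b, t.c, v};
        std::sort(q, q + 4);
        col.push_back(
            CoKey{val, (((int64_t)q[0] * N + q[1]) * N + q[2]) * N + q[3]});
      }
      std::sort(col.begin(), col.end(), cokey_less);
      for (;;) {
        if (col.empty()) break;  // essential 2-cycle (absent at full scale)
        const CoKey piv = col.front();
        auto it = pivot_owner.find(piv.id);
        if (it == pivot_owner.end()) {
          pivot_owner.emplace(piv.id, (int)stored.size());
          stored.push_back(col);
          if (piv.v > t.v) {
            b2.push_back(t.v);
            d2.push_back(piv.v);
          }
          break;
        }
        sym_diff(col, stored[it->second], tmp);
      }
    }
  }
  out[2] = bars_matrix(b2, d2);
  return out;
}
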