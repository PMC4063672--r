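// Core combinatorial machinery: collection of coactivity simplices from
// binned spike events, and persistent homology of the resulting time-filtered
// complex over Z/2 (standard column reduction with the clearing optimisation).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Vertex ids are 1-based and must fit in 16 bits; a simplex of dimension <= 3
// packs its (sorted) vertices into one 64-bit key. Keys are kept in per-dim
// maps so equal packings of different cardinality cannot collide.
static inline uint64_t pack2(int a, int b) {
  return (static_cast<uint64_t>(a) << 16) | static_cast<uint64_t>(b);
}
static inline uint64_t pack3(int a, int b, int c) {
  return (static_cast<uint64_t>(a) << 32) | (static_cast<uint64_t>(b) << 16) |
         static_cast<uint64_t>(c);
}
static inline uint64_t pack4(int a, int b, int c, int d) {
  return (static_cast<uint64_t>(a) << 48) | (static_cast<uint64_t>(b) << 32) |
         (static_cast<uint64_t>(c) << 16) | static_cast<uint64_t>(d);
}

// [[Rcpp::export]]
List cpp_collect_simplices(List bins, NumericVector bin_times, int max_dim) {
  if (max_dim < 0 || max_dim > 3) stop("max_dim must be between 0 and 3");
  const int nb = bins.size();
  if (nb != bin_times.size()) stop("bins and bin_times length mismatch");

  std::unordered_map<uint64_t, double> seen0, seen1, seen2, seen3;
  // remember insertion order so output is deterministic
  std::vector<uint64_t> ord0, ord1, ord2, ord3;

  for (int b = 0; b < nb; ++b) {
    IntegerVector cells = bins[b];
    const double t = bin_times[b];
    const int m = cells.size();
    for (int i = 0; i < m; ++i) {
      if (cells[i] < 1 || cells[i] > 65535) stop("cell ids must be in [1, 65535]");
      uint64_t k = static_cast<uint64_t>(cells[i]);
      if (seen0.emplace(k, t).second) ord0.push_back(k);
    }
    if (max_dim >= 1) {
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j) {
          uint64_t k = pack2(cells[i], cells[j]);
          if (seen1.emplace(k, t).second) ord1.push_back(k);
        }
    }
    if (max_dim >= 2 && m >= 3) {
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          for (int l = j + 1; l < m; ++l) {
            uint64_t k = pack3(cells[i], cells[j], cells[l]);
            if (seen2.emplace(k, t).second) ord2.push_back(k);
          }
    }
    if (max_dim >= 3 && m >= 4) {
      for (int i = 0; i < m; ++i)
        for (int j = i + 1; j < m; ++j)
          for (int l = j + 1; l < m; ++l)
            for (int q = l + 1; q < m; ++q) {
              uint64_t k = pack4(cells[i], cells[j], cells[l], cells[q]);
              if (seen3.emplace(k, t).second) ord3.push_back(k);
            }
    }
  }

  const size_t n = ord0.size() + ord1.size() + ord2.size() + ord3.size();
  IntegerMatrix verts(n, 4);
  IntegerVector dims(n);
  NumericVector births(n);
  size_t r = 0;
  for (uint64_t k : ord0) {
    verts(r, 0) = static_cast<int>(k & 0xFFFF);
    dims[r] = 0; births[r] = seen0[k]; ++r;
  }
  for (uint64_t k : ord1) {
    verts(r, 0) = static_cast<int>((k >> 16) & 0xFFFF);
    verts(r, 1) = static_cast<int>(k & 0xFFFF);
    dims[r] = 1; births[r] = seen1[k]; ++r;
  }
  for (uint64_t k : ord2) {
    verts(r, 0) = static_cast<int>((k >> 32) & 0xFFFF);
    verts(r, 1) = static_cast<int>((k >> 16) & 0xFFFF);
    verts(r, 2) = static_cast<int>(k & 0xFFFF);
    dims[r] = 2; births[r] = seen2[k]; ++r;
  }
  for (uint64_t k : ord3) {
    verts(r, 0) = static_cast<int>((k >> 48) & 0xFFFF);
    verts(r, 1) = static_cast<int>((k >> 32) & 0xFFFF);
    verts(r, 2) = static_cast<int>((k >> 16) & 0xFFFF);
    verts(r, 3) = static_cast<int>(k & 0xFFFF);
    dims[r] = 3; births[r] = seen3[k]; ++r;
  }
  return List::create(_["verts"] = verts, _["dim"] = dims, _["birth"] = births);
}

static inline std::vector<int> symdiff(const std::vector<int>& a,
                                       const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// Persistence pairs of a filtered complex. Rows must be sorted so that every
// face precedes its cofaces (sorting by (birth, dim) suffices for a valid
// filtration). Returns pairs of row indices (1-based) and the unpaired
// (essential) rows.
// [[Rcpp::export]]
List cpp_persistence_pairs(IntegerMatrix verts, IntegerVector dims,
                           NumericVector births) {
  const int n = verts.nrow();
  if (n == 0)
    return List::create(_["birth_idx"] = IntegerVector(0),
                        _["death_idx"] = IntegerVector(0),
                        _["essential_idx"] = IntegerVector(0));

  int maxd = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && births[i] < births[i - 1]) stop("rows not sorted by birth");
    if (dims[i] > maxd) maxd = dims[i];
  }

  // key -> row index, per dimension
  std::vector<std::unordered_map<uint64_t, int>> index(maxd + 1);
  for (int i = 0; i < n; ++i) {
    uint64_t k;
    switch (dims[i]) {
      case 0: k = static_cast<uint64_t>(verts(i, 0)); break;
      case 1: k = pack2(verts(i, 0), verts(i, 1)); break;
      case 2: k = pack3(verts(i, 0), verts(i, 1), verts(i, 2)); break;
      default: k = pack4(verts(i, 0), verts(i, 1), verts(i, 2), verts(i, 3));
    }
    index[dims[i]][k] = i;
  }

  std::vector<std::vector<int>> cols(n);
  std::vector<int> pivot(n, -1);
  std::vector<char> cleared(n, 0), is_death(n, 0), is_killed(n, 0);
  std::vector<int> birth_idx, death_idx;

  for (int d = maxd; d >= 1; --d) {
    for (int j = 0; j < n; ++j) {
      if (dims[j] != d || cleared[j]) continue;
      // boundary of simplex j: drop one vertex at a time
      std::vector<int> col;
      col.reserve(d + 1);
      int v[4] = {verts(j, 0), verts(j, 1), verts(j, 2), verts(j, 3)};
      for (int omit = 0; omit <= d; ++omit) {
        uint64_t k;
        if (d == 1) k = static_cast<uint64_t>(v[1 - omit]);
        else if (d == 2) {
          int a[2]; int p = 0;
          for (int q = 0; q < 3; ++q) if (q != omit) a[p++] = v[q];
          k = pack2(a[0], a[1]);
        } else {
          int a[3]; int p = 0;
          for (int q = 0; q < 4; ++q) if (q != omit) a[p++] = v[q];
          k = pack3(a[0], a[1], a[2]);
        }
        auto it = index[d - 1].find(k);
        if (it == index[d - 1].end()) stop("missing face: complex not closed");
        if (it->second > j) stop("face born after coface: invalid filtration order");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int k = pivot[low];
        if (k < 0) break;
        col = symdiff(col, cols[k]);
      }
      if (!col.empty()) {
        int low = col.back();
        pivot[low] = j;
        is_death[j] = 1;
        is_killed[low] = 1;
        cleared[low] = 1;  // clearing: the paired face need not be reduced
        birth_idx.push_back(low + 1);
        death_idx.push_back(j + 1);
        cols[j] = std::move(col);
      }
    }
  }

  std::vector<int> essential;
  for (int i = 0; i < n; ++i)
    if (!is_death[i] && !is_killed[i]) essential.push_back(i + 1);

  return List::create(_["birth_idx"] = wrap(birth_idx),
                      _["death_idx"] = wrap(death_idx),
                      _["essential_idx"] = wrap(essential));
}
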