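#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Per-gene neighborhood of a focal cell: the m cells whose expression values
// are nearest to the focal cell's value, taken as a contiguous window in the
// (value, cell-index) sort order. Ties in value distance take the lower-rank
// side so the window is deterministic.
static inline void window_bounds(const std::vector<double>& v, int n, int p,
                                 int m, int& lo, int& hi) {
  lo = p;
  hi = p;
  int cnt = 1;
  while (cnt < m) {
    bool take_left;
    if (lo == 0)
      take_left = false;
    else if (hi == n - 1)
      take_left = true;
    else
      take_left = (v[p] - v[lo - 1]) <= (v[hi + 1] - v[p]);
    if (take_left) --lo; else ++hi;
    ++cnt;
  }
}

// Stable sort order of cells by (value, index) for one gene.
static void value_order(const double* x, int n, std::vector<int>& ord) {
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
}

// [[Rcpp::export(name = ".csn_neighborhood")]]
IntegerVector csn_neighborhood(NumericVector x, int k, int m) {
  int n = x.size();
  if (k < 1 || k > n) stop("cell index out of range");
  if (m < 1 || m > n) stop("neighborhood size out of range");
  std::vector<int> ord;
  value_order(REAL(x), n, ord);
  std::vector<double> v(n);
  std::vector<int> pos(n);
  for (int q = 0; q < n; ++q) {
    v[q] = x[ord[q]];
    pos[ord[q]] = q;
  }
  int lo, hi;
  window_bounds(v, n, pos[k - 1], m, lo, hi);
  IntegerVector out(hi - lo + 1);
  for (int q = lo; q <= hi; ++q) out[q - lo] = ord[q] + 1;
  return out;
}

// Build edge lists for a set of cells. expr is genes x cells (preprocessed).
// An edge i-j is called in cell k when the neighborhood-overlap count n_ij
// reaches min_nij (the threshold encodes the configured edge rule, since both
// margins are fixed at m). Constant genes (skip[g] true) take part in no edge.
// Returns one integer matrix (n_edges x 3: gene_i, gene_j, n_ij) per cell.
// [[Rcpp::export(name = ".csn_edges")]]
List csn_edges(NumericMatrix expr, IntegerVector cells, int m, double min_nij,
               LogicalVector skip) {
  const int nG = expr.nrow(), nC = expr.ncol();
  if (m < 1 || m > nC) stop("neighborhood size out of range");
  const int words = (nC + 63) / 64;

  // per-gene sorted values and cell order, computed once
  std::vector<std::vector<int> > ord(nG);
  std::vector<std::vector<double> > vals(nG);
  std::vector<std::vector<int> > pos(nG);
  std::vector<double> row(nC);
  for (int g = 0; g < nG; ++g) {
    if (skip[g]) continue;
    for (int c = 0; c < nC; ++c) row[c] = expr(g, c);
    value_order(row.data(), nC, ord[g]);
    vals[g].resize(nC);
    pos[g].resize(nC);
    for (int q = 0; q < nC; ++q) {
      vals[g][q] = row[ord[g][q]];
      pos[g][ord[g][q]] = q;
    }
  }

  std::vector<uint64_t> bits((size_t)nG * words);
  std::vector<int> ei, ej, ecnt;
  List out(cells.size());

  for (int ci = 0; ci < cells.size(); ++ci) {
    int k = cells[ci] - 1;
    if (k < 0 || k >= nC) stop("cell index out of range");
    std::fill(bits.begin(), bits.end(), 0ULL);
    for (int g = 0; g < nG; ++g) {
      if (skip[g]) continue;
      int lo, hi;
      window_bounds(vals[g], nC, pos[g][k], m, lo, hi);
      uint64_t* bg = &bits[(size_t)g * words];
      for (int q = lo; q <= hi; ++q) {
        int c = ord[g][q];
        bg[c >> 6] |= (1ULL << (c & 63));
      }
    }
    ei.clear(); ej.clear(); ecnt.clear();
    for (int i = 0; i < nG - 1; ++i) {
      if (skip[i]) continue;
      const uint64_t* bi = &bits[(size_t)i * words];
      for (int j = i + 1; j < nG; ++j) {
        if (skip[j]) continue;
        const uint64_t* bj = &bits[(size_t)j * words];
        int cnt = 0;
        for (int w = 0; w < words; ++w)
          cnt += __builtin_popcountll(bi[w] & bj[w]);
        if ((double)cnt >= min_nij) {
          ei.push_back(i + 1);
          ej.push_back(j + 1);
          ecnt.push_back(cnt);
        }
      }
    }
    IntegerMatrix em(ei.size(), 3);
    for (size_t e = 0; e < ei.size(); ++e) {
      em(e, 0) = ei[e];
      em(e, 1) = ej[e];
      em(e, 2) = ecnt[e];
    }
    out[ci] = em;
  }
  return out;
}
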