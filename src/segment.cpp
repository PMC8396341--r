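// Segmentation helpers: 8-connected component labelling, local-maximum
// seed picking with greedy minimum-separation suppression, and a seeded
// watershed (priority flood on the negated density, restricted to a mask).
#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

static const int DX8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int d = 0; d < 8; ++d) {
          int ni = p.first + DX8[d], nj = p.second + DY8[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// Local maxima of `values` inside `mask`: a pixel whose value is maximal
// over the Chebyshev window of radius `radius`, with greedy suppression so
// surviving peaks are pairwise separated by more than `min_sep` (Euclidean).
// Returns 1-based (row, col) pairs ordered by decreasing value.
// [[Rcpp::export(name = ".local_maxima")]]
IntegerMatrix local_maxima(const NumericMatrix& values, const IntegerMatrix& mask,
                           int radius, double min_sep) {
  const int H = values.nrow(), W = values.ncol();
  std::vector<std::pair<double, std::pair<int, int> > > cand;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      double v = values(i, j);
      if (v <= 0) continue;
      bool is_max = true;
      for (int dj = -radius; dj <= radius && is_max; ++dj) {
        for (int di = -radius; di <= radius; ++di) {
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (values(ni, nj) > v) { is_max = false; break; }
        }
      }
      if (is_max) cand.push_back(std::make_pair(v, std::make_pair(i, j)));
    }
  }
  std::stable_sort(cand.begin(), cand.end(),
                   [](const std::pair<double, std::pair<int, int> >& a,
                      const std::pair<double, std::pair<int, int> >& b) {
                     return a.first > b.first;
                   });
  std::vector<std::pair<int, int> > kept;
  for (size_t k = 0; k < cand.size(); ++k) {
    bool ok = true;
    for (size_t m = 0; m < kept.size(); ++m) {
      double di = cand[k].second.first - kept[m].first;
      double dj = cand[k].second.second - kept[m].second;
      if (std::sqrt(di * di + dj * dj) < min_sep) { ok = false; break; }
    }
    if (ok) kept.push_back(cand[k].second);
  }
  IntegerMatrix out(kept.size(), 2);
  for (size_t k = 0; k < kept.size(); ++k) {
    out(k, 0) = kept[k].first + 1;
    out(k, 1) = kept[k].second + 1;
  }
  return out;
}

struct WsEntry {
  double priority;  // negated density: lower density floods later
  long order;       // FIFO tie-break for plateaus
  int i, j, label;
};
struct WsCompare {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;
    return a.order > b.order;
  }
};

// Seeded watershed: floods `mask` from `seeds` (1-based row/col pairs, each
// row one seed, labelled 1..n in order) following decreasing density.
// Mask pixels unreachable from any seed keep label 0.
// [[Rcpp::export(name = ".watershed")]]
IntegerMatrix watershed_seeded(const NumericMatrix& density,
                               const IntegerMatrix& mask,
                               const IntegerMatrix& seeds) {
  const int H = density.nrow(), W = density.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  long order = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0) - 1, j = seeds(s, 1) - 1;
    if (i < 0 || i >= H || j < 0 || j >= W || !mask(i, j))
      stop("watershed seed %d outside the mask", s + 1);
    pq.push({-density(i, j), order++, i, j, s + 1});
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (lab(e.i, e.j)) continue;
    lab(e.i, e.j) = e.label;
    for (int d = 0; d < 8; ++d) {
      int ni = e.i + DX8[d], nj = e.j + DY8[d];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (mask(ni, nj) && !lab(ni, nj))
        pq.push({-density(ni, nj), order++, ni, nj, e.label});
    }
  }
  return lab;
}
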