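#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Median filter with edge-replicated borders. Windows are k x k, k odd.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, const int k) {
  const int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> win(k * k);
  const int mid = (k * k) / 2; // odd count -> single middle element
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          win[n++] = img(ci, cj);
        }
      }
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      out(i, j) = win[mid];
    }
  }
  return out;
}

// Hysteresis edge linking: keep weak-or-strong pixels 8-connected to a
// strong pixel. `strong` must be a subset of `weak`.
// [[Rcpp::export(name = ".hysteresis_cpp")]]
LogicalMatrix hysteresis_cpp(const LogicalMatrix& strong,
                             const LogicalMatrix& weak) {
  const int nr = strong.nrow(), nc = strong.ncol();
  LogicalMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (strong(i, j)) { out(i, j) = true; q.push(std::make_pair(i, j)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int i = p.first + di, j = p.second + dj;
        if (i < 0 || j < 0 || i >= nr || j >= nc) continue;
        if (weak(i, j) && !out(i, j)) {
          out(i, j) = true;
          q.push(std::make_pair(i, j));
        }
      }
    }
  }
  return out;
}

// Largest 8-connected component of a binary mask (all false -> all false).
// [[Rcpp::export(name = ".largest_component_cpp")]]
LogicalMatrix largest_component_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> lab(static_cast<size_t>(nr) * nc, 0);
  int next = 0, best_lab = 0;
  long best_size = 0;
  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab[static_cast<size_t>(j0) * nr + i0]) continue;
      ++next;
      long size = 0;
      lab[static_cast<size_t>(j0) * nr + i0] = next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        ++size;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int i = p.first + di, j = p.second + dj;
            if (i < 0 || j < 0 || i >= nr || j >= nc) continue;
            size_t idx = static_cast<size_t>(j) * nr + i;
            if (mask(i, j) && !lab[idx]) {
              lab[idx] = next;
              q.push(std::make_pair(i, j));
            }
          }
        }
      }
      if (size > best_size) { best_size = size; best_lab = next; }
    }
  }
  LogicalMatrix out(nr, nc);
  if (best_lab > 0)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        out(i, j) = lab[static_cast<size_t>(j) * nr + i] == best_lab;
  return out;
}
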