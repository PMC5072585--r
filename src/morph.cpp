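#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first search.
// Labels are assigned in column-major first-encounter order, so the result
// is deterministic for a given mask. connectivity is 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + dr8[k], nj = cj + dc8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill enclosed background holes: background is flood-filled (4-connected)
// from the image border; anything not reached becomes foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reached(nr, nc);
  std::vector<int> stack;
  auto push = [&](int i, int j) {
    if (!mask(i, j) && !reached(i, j)) {
      reached(i, j) = true;
      stack.push_back(i + j * nr);
    }
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int ci = idx % nr, cj = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = ci + dr[k], nj = cj + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      push(ni, nj);
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reached(i, j);
  return out;
}

// Binary erosion/dilation with an arbitrary structuring element given as
// row/column offsets. Out-of-frame neighbours count as background, the
// standard convention for object masks.
// [[Rcpp::export(name = ".binary_morph")]]
LogicalMatrix binary_morph(const LogicalMatrix& mask, const IntegerVector& dr,
                           const IntegerVector& dc, bool erode) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int m = dr.size();
  LogicalMatrix out(nr, nc);
  // iterate over foreground pixels only: erosion output is a subset of the
  // foreground, and dilation is a sparse scatter of the structuring element
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      if (erode) {
        bool all_in = true;
        for (int k = 0; k < m; ++k) {
          int ni = i + dr[k], nj = j + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || !mask(ni, nj)) {
            all_in = false;
            break;
          }
        }
        out(i, j) = all_in;
      } else {
        for (int k = 0; k < m; ++k) {
          int ni = i - dr[k], nj = j - dc[k];
          if (ni >= 0 && ni < nr && nj >= 0 && nj < nc)
            out(ni, nj) = true;
        }
      }
    }
  }
  return out;
}
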