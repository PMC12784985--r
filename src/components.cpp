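#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labeling by iterative flood fill.
// Returns an integer matrix: 0 = background, 1..n = component ids.
// [[Rcpp::export(name = "cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background connected (4-conn) to the image border
// stays background; enclosed background becomes foreground.
// [[Rcpp::export(name = "cc_fill_holes")]]
LogicalMatrix cc_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc); // reachable background
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool border = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (border && !mask(r, c) && !outside(r, c)) {
        outside(r, c) = true;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          const int dr[4] = {-1, 1, 0, 0};
          const int dc[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            int r2 = rr + dr[k], c2 = cc + dc[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (!mask(r2, c2) && !outside(r2, c2)) {
              outside(r2, c2) = true;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || !outside(r, c);
  return out;
}
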