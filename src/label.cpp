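// 8-connected component labeling of a binary mask (spots = TRUE), matching
// the diagonal-touch behaviour of standard particle-analysis tools.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);  // 0 = background
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
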