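#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a logical matrix by breadth-first search.
// connectivity must be 4 or 8. Returns an integer matrix with 0 for
// background and labels 1..k in first-encounter (column-major) order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
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

// Accumulate grey-level pair counts for all ordered pixel pairs (p, q) with
// both pixels inside the mask and offset q - p drawn from the supplied list.
// levels is the 0-based quantized image (values in 0..n_levels-1, only read
// inside the mask). Returns an n_levels x n_levels count matrix.
// [[Rcpp::export(name = ".glcm_accumulate")]]
NumericMatrix glcm_accumulate(const IntegerMatrix& levels,
                              const LogicalMatrix& mask,
                              const IntegerMatrix& offsets,
                              int n_levels) {
  const int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix acc(n_levels, n_levels);
  const int noff = offsets.nrow();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int li = levels(r, c);
      for (int k = 0; k < noff; ++k) {
        const int r2 = r + offsets(k, 0), c2 = c + offsets(k, 1);
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!mask(r2, c2)) continue;
        acc(li, levels(r2, c2)) += 1.0;
      }
    }
  }
  return acc;
}
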