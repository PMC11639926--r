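#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect-pad index into [0, n).  Mirrors without repeating the edge sample
// beyond once (symmetric / half-sample reflection), matching the usual
// "reflect" boundary mode of image-processing libraries.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Sliding-window median with reflect padding.  For an even window dimension
// the output pixel sits at position ceil(h/2), ceil(w/2) (1-based) inside the
// window, i.e. the window extends one pixel further up/left than down/right.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int wh, int ww) {
  int nr = img.nrow(), nc = img.ncol();
  if (wh < 1 || ww < 1) stop("window dimensions must be >= 1");
  if (wh > nr || ww > nc) stop("window larger than image");
  // offsets of the window relative to the output pixel
  int up = (wh + 1) / 2 - 1;      // rows above (anchor at ceil(h/2))
  int down = wh - 1 - up;         // rows below
  int left = (ww + 1) / 2 - 1;
  int right = ww - 1 - left;

  NumericMatrix out(nr, nc);
  std::vector<double> buf(static_cast<size_t>(wh) * ww);
  size_t m = buf.size();
  // upper-middle order statistic; for even window sizes this keeps the
  // output inside the input value set (no averaging of the two middles)
  size_t k = m / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t t = 0;
      for (int dj = -left; dj <= right; ++dj) {
        int cj = reflect_index(j + dj, nc);
        for (int di = -up; di <= down; ++di) {
          int ci = reflect_index(i + di, nr);
          buf[t++] = img(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(i, j) = buf[k];
    }
  }
  return out;
}

// Mask-aware sliding-window median: the window sample is restricted to
// foreground pixels, so values outside the mask never contaminate medians
// near the foreground boundary.  Background pixels are left at 0.
// [[Rcpp::export]]
NumericMatrix median_filter_masked_cpp(NumericMatrix img, LogicalMatrix mask,
                                       int wh, int ww) {
  int nr = img.nrow(), nc = img.ncol();
  if (wh < 1 || ww < 1) stop("window dimensions must be >= 1");
  if (wh > nr || ww > nc) stop("window larger than image");
  if (mask.nrow() != nr || mask.ncol() != nc) stop("mask shape mismatch");
  int up = (wh + 1) / 2 - 1;
  int down = wh - 1 - up;
  int left = (ww + 1) / 2 - 1;
  int right = ww - 1 - left;

  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(static_cast<size_t>(wh) * ww);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { out(i, j) = 0.0; continue; }
      buf.clear();
      for (int dj = -left; dj <= right; ++dj) {
        int cj = reflect_index(j + dj, nc);
        for (int di = -up; di <= down; ++di) {
          int ci = reflect_index(i + di, nr);
          if (mask(ci, cj)) buf.push_back(img(ci, cj));
        }
      }
      size_t k = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(i, j) = buf[k];
    }
  }
  return out;
}

// Connected-component labelling of a logical mask, 4- or 8-connectivity.
// Two-pass union-find; labels are 1..n_components in raster discovery order,
// 0 is background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int lbl = 0;
      // previously-scanned neighbours in column-major raster order
      if (i > 0 && mask(i - 1, j)) lbl = lab(i - 1, j);
      if (j > 0 && mask(i, j - 1)) {
        int l2 = lab(i, j - 1);
        if (lbl) unite(lbl, l2); else lbl = l2;
      }
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) {
          int l2 = lab(i - 1, j - 1);
          if (lbl) unite(lbl, l2); else lbl = l2;
        }
        if (i < nr - 1 && mask(i + 1, j - 1)) {
          int l2 = lab(i + 1, j - 1);
          if (lbl) unite(lbl, l2); else lbl = l2;
        }
      }
      if (!lbl) {
        lbl = next++;
        parent.push_back(lbl);
      }
      lab(i, j) = lbl;
    }
  }
  // second pass: flatten and renumber consecutively
  std::vector<int> remap(next, 0);
  int count = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j)) {
        int r = find(lab(i, j));
        if (!remap[r]) remap[r] = ++count;
        lab(i, j) = remap[r];
      }
  return lab;
}
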