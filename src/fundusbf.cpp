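#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labeling of a logical mask by iterative flood fill.
// Labels are 1-based; background (false) pixels get 0.
// [[Rcpp::export(name = ".label_components4")]]
IntegerMatrix label_components4(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * h);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % h, pj = p / h;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = pi + di[k], nj = pj + dj[k];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * h);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Fill interior holes of a mask: background pixels whose 4-connected
// component does not touch the image border become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix inv(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      inv(i, j) = !mask(i, j);
  IntegerMatrix lab = label_components4(inv);
  int ncomp = lab.attr("n_components");
  std::vector<bool> touches(ncomp + 1, false);
  for (int i = 0; i < h; ++i) {
    if (lab(i, 0)) touches[lab(i, 0)] = true;
    if (lab(i, w - 1)) touches[lab(i, w - 1)] = true;
  }
  for (int j = 0; j < w; ++j) {
    if (lab(0, j)) touches[lab(0, j)] = true;
    if (lab(h - 1, j)) touches[lab(h - 1, j)] = true;
  }
  LogicalMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = mask(i, j) || (lab(i, j) && !touches[lab(i, j)]);
  return out;
}

// Masked sliding-window median over integer images in [0, 255], computed
// with a 256-bin histogram updated as the window slides along each row.
// Only in-mask, in-bounds neighbors enter the histogram; output is 0 off
// the mask. Even member counts take the lower median.
// [[Rcpp::export(name = ".masked_median")]]
NumericMatrix masked_median(IntegerMatrix img, LogicalMatrix mask, int window) {
  int h = img.nrow(), w = img.ncol();
  int r = (window - 1) / 2;
  NumericMatrix out(h, w);
  std::vector<int> hist(256);

  for (int i = 0; i < h; ++i) {
    int r0 = std::max(0, i - r), r1 = std::min(h - 1, i + r);
    std::fill(hist.begin(), hist.end(), 0);
    int count = 0;
    // seed histogram with columns [0, r]
    for (int j = 0; j <= std::min(w - 1, r); ++j)
      for (int ii = r0; ii <= r1; ++ii)
        if (mask(ii, j)) { ++hist[img(ii, j)]; ++count; }
    for (int j = 0; j < w; ++j) {
      if (j > 0) {
        int add = j + r, rem = j - r - 1;
        if (add < w)
          for (int ii = r0; ii <= r1; ++ii)
            if (mask(ii, add)) { ++hist[img(ii, add)]; ++count; }
        if (rem >= 0)
          for (int ii = r0; ii <= r1; ++ii)
            if (mask(ii, rem)) { --hist[img(ii, rem)]; --count; }
      }
      if (!mask(i, j) || count == 0) { out(i, j) = 0; continue; }
      int k = (count + 1) / 2;  // lower median
      int acc = 0, v = 0;
      for (; v < 256; ++v) { acc += hist[v]; if (acc >= k) break; }
      out(i, j) = v;
    }
  }
  return out;
}
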