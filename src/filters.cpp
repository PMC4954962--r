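#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// 4-connected component labelling of a logical mask.
// Background = 0, components numbered 1..n in raster order of first pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        // 4-neighbours
        if (rr > 0      && mask(rr - 1, cc) && lab(rr - 1, cc) == 0) { lab(rr - 1, cc) = next; stack.push_back(cc * nr + rr - 1); }
        if (rr < nr - 1 && mask(rr + 1, cc) && lab(rr + 1, cc) == 0) { lab(rr + 1, cc) = next; stack.push_back(cc * nr + rr + 1); }
        if (cc > 0      && mask(rr, cc - 1) && lab(rr, cc - 1) == 0) { lab(rr, cc - 1) = next; stack.push_back((cc - 1) * nr + rr); }
        if (cc < nc - 1 && mask(rr, cc + 1) && lab(rr, cc + 1) == 0) { lab(rr, cc + 1) = next; stack.push_back((cc + 1) * nr + rr); }
      }
    }
  }
  return lab;
}

static void run_minmax_1d(const double* x, double* out, int n, int radius, bool take_min) {
  // Sliding window extreme via monotone deque of indices.
  std::deque<int> q;
  int w = radius; // window = [i - radius, i + radius]
  // process with a lead of `radius`
  for (int i = 0; i < n + radius; ++i) {
    if (i < n) {
      while (!q.empty() &&
             (take_min ? x[q.back()] >= x[i] : x[q.back()] <= x[i]))
        q.pop_back();
      q.push_back(i);
    }
    int center = i - w;
    if (center >= 0) {
      while (q.front() < center - radius) q.pop_front();
      out[center] = x[q.front()];
    }
  }
}

static NumericMatrix sep_filter(const NumericMatrix& img, int radius, bool take_min) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> buf(std::max(nr, nc)), res(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) buf[r] = img(r, c);
    run_minmax_1d(buf.data(), res.data(), nr, radius, take_min);
    for (int r = 0; r < nr; ++r) tmp(r, c) = res[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) buf[c] = tmp(r, c);
    run_minmax_1d(buf.data(), res.data(), nc, radius, take_min);
    for (int c = 0; c < nc; ++c) out(r, c) = res[c];
  }
  return out;
}

// Grayscale erosion with a (2*radius+1)^2 square structuring element.
// [[Rcpp::export(name = ".min_filter")]]
NumericMatrix min_filter_cpp(NumericMatrix img, int radius) {
  return sep_filter(img, radius, true);
}

// Grayscale dilation with a (2*radius+1)^2 square structuring element.
// [[Rcpp::export(name = ".max_filter")]]
NumericMatrix max_filter_cpp(NumericMatrix img, int radius) {
  return sep_filter(img, radius, false);
}
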