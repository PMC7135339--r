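#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Edge replication: clamp an index into [0, n-1].
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Grayscale erosion by a non-flat structuring element given as offset
// triplets (dy, dx, height): e(p) = min_u f(p + u) - h(u).
// [[Rcpp::export]]
NumericMatrix cpp_erode_nonflat(NumericMatrix img, IntegerVector dy,
                                IntegerVector dx, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double cand = img(clampi(i + dy[k], nr), clampi(j + dx[k], nc)) - h[k];
        if (cand < v) v = cand;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Grayscale dilation by the same element: d(p) = max_u f(p - u) + h(u).
// [[Rcpp::export]]
NumericMatrix cpp_dilate_nonflat(NumericMatrix img, IntegerVector dy,
                                 IntegerVector dx, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_NegInf;
      for (int k = 0; k < m; ++k) {
        double cand = img(clampi(i - dy[k], nr), clampi(j - dx[k], nc)) + h[k];
        if (cand > v) v = cand;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Flat minimum filter over an arbitrary offset neighborhood.
// [[Rcpp::export]]
NumericMatrix cpp_min_filter(NumericMatrix img, IntegerVector dy,
                             IntegerVector dx) {
  int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double cand = img(clampi(i + dy[k], nr), clampi(j + dx[k], nc));
        if (cand < v) v = cand;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Mean filter over an arbitrary offset neighborhood (edge replication,
// so border pixels average the same number of samples).
// [[Rcpp::export]]
NumericMatrix cpp_mean_filter(NumericMatrix img, IntegerVector dy,
                              IntegerVector dx) {
  int nr = img.nrow(), nc = img.ncol(), m = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < m; ++k)
        s += img(clampi(i + dy[k], nr), clampi(j + dx[k], nc));
      out(i, j) = s / m;
    }
  }
  return out;
}

// Separable convolution: 1-D kernel along rows (within a row, across
// columns) then along columns, with edge replication. Kernels are
// symmetric or antisymmetric and indexed -r..r.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(NumericMatrix img, NumericVector kx,
                           NumericVector ky) {
  int nr = img.nrow(), nc = img.ncol();
  int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int k = -rx; k <= rx; ++k)
        s += kx[k + rx] * img(i, clampi(j + k, nc));
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = -ry; k <= ry; ++k)
        s += ky[k + ry] * tmp(clampi(i + k, nr), j);
      out(i, j) = s;
    }
  return out;
}

// Connected-component labeling by breadth-first flood fill.
// connectivity is 4 or 8; labels are 1..n in raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int *dy = (connectivity == 8) ? dy8 : dy4;
  const int *dx = (connectivity == 8) ? dx8 : dx4;
  int nn = (connectivity == 8) ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int ii = p.first + dy[k], jj = p.second + dx[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
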