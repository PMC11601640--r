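#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <functional>

using namespace Rcpp;

// Separable Gaussian blur with reflective boundaries. Kernel truncated at
// 3 sigma; sigma <= 0 returns the input unchanged.
// [[Rcpp::export(name = ".cf_gaussian_blur")]]
NumericMatrix cf_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (y)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[d + radius] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along cols (x)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int jj = j + d;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        acc += k[d + radius] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// 8-connected component labelling by two-pass union-find.
// [[Rcpp::export(name = ".cf_label_components")]]
IntegerMatrix cf_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int x) {
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
      int best = 0;
      // scan already-visited 8-neighbours (previous column, and above)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      for (auto& p : nb) {
        int ii = p[0], jj = p[1];
        if (ii < 0 || ii >= nr || jj < 0) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = next++;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      int r = find(lab(i, j));
      if (remap[r] == 0) remap[r] = ++nlab;
      lab(i, j) = remap[r];
    }
  return lab;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d) {
  // Felzenszwalb & Huttenlocher lower-envelope squared distance transform
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sdist = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (sdist <= z[k]) {
      --k;
      sdist = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = sdist;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
// pixel of `mask`. Pixels inside the mask get 0. All-FALSE masks give Inf.
// Uses a large finite sentinel internally so parabola intersections stay
// well defined (FH squared distances never exceed nr^2 + nc^2 << BIG).
// [[Rcpp::export(name = ".cf_edt")]]
NumericMatrix cf_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e15;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g(i, j) = mask(i, j) ? 0.0 : BIG;

  // columns first
  {
    std::vector<double> f(nr), d(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) f[i] = g(i, j);
      edt_1d(f, d);
      for (int i = 0; i < nr; ++i) g(i, j) = d[i];
    }
  }
  // then rows
  NumericMatrix out(nr, nc);
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = std::min(g(i, j), BIG);
    edt_1d(fr, dr);
    for (int j = 0; j < nc; ++j)
      out(i, j) = dr[j] >= BIG * 0.5 ? R_PosInf : std::sqrt(dr[j]);
  }
  return out;
}
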