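#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Two-pass union-find connected-component labelling of a logical matrix.
// conn = 4 or 8. Labels are 1..k in order of first (column-major) occurrence.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously-visited neighbours in column-major order
      int nb[4][2] = {{i - 1, j}, {i, j - 1}, {i - 1, j - 1}, {i + 1, j - 1}};
      int nnb = (conn == 8) ? 4 : 2;
      int cur = 0;
      for (int k = 0; k < nnb; ++k) {
        int ii = nb[k][0], jj = nb[k][1];
        if (ii < 0 || jj < 0 || ii >= nr) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (cur == 0) cur = l;
          else uf_union(parent, cur, l);
        }
      }
      if (cur == 0) {
        cur = next++;
        parent.push_back(cur);
      }
      lab(i, j) = cur;
    }
  }
  // flatten and renumber 1..k
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (remap[r] == 0) remap[r] = ++k;
      lab(i, j) = remap[r];
    }
  lab.attr("n_components") = k;
  return lab;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Distance of each foreground pixel to the nearest background pixel;
// everything outside the matrix counts as background.

static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix mask) {
  // pad by one background ring so the image border acts as background
  int nr = mask.nrow() + 2, nc = mask.ncol() + 2;
  const double INF = 1e20;
  std::vector<double> g(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool fg = (i > 0 && j > 0 && i < nr - 1 && j < nc - 1) ? (bool)mask(i - 1, j - 1) : false;
      g[i + j * nr] = fg ? INF : 0.0;
    }
  // columns
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g[i + j * nr];
    edt_1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g[i + j * nr] = d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g[i + j * nr];
    edt_1d(f, d, nc);
    for (int j = 0; j < nc; ++j) g[i + j * nr] = d[j];
  }
  NumericMatrix out(mask.nrow(), mask.ncol());
  for (int j = 0; j < mask.ncol(); ++j)
    for (int i = 0; i < mask.nrow(); ++i)
      out(i, j) = g[(i + 1) + (j + 1) * nr];
  return out;
}
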