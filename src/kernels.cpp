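#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Synthetic BOLD assembly in one pass: AR(1) noise (R RNG, stationary
// start, per-voxel sd) plus baseline plus a low-rank deterministic
// structure L (nv x p) * R (p x ns).
// [[Rcpp::export(name = ".bold_noise_signal")]]
NumericMatrix bold_noise_signal(NumericVector sd_row, int ns, double phi,
                                double baseline, NumericMatrix L,
                                NumericMatrix R) {
  const int nv = sd_row.size(), p = L.ncol();
  NumericMatrix Y(nv, ns);
  std::vector<double> state(nv);
  const double fac = std::sqrt(1.0 - phi * phi);
  for (int s = 0; s < ns; ++s) {
    double *cur = &Y(0, s);
    if (s == 0) {
      for (int v = 0; v < nv; ++v) state[v] = R::rnorm(0.0, sd_row[v]);
    } else {
      for (int v = 0; v < nv; ++v)
        state[v] = phi * state[v] + R::rnorm(0.0, fac * sd_row[v]);
    }
    for (int v = 0; v < nv; ++v) cur[v] = state[v] + baseline;
    for (int j = 0; j < p; ++j) {
      const double r = R(j, s);
      if (r == 0.0) continue;
      const double *lj = &L(0, j);
      for (int v = 0; v < nv; ++v) cur[v] += lj[v] * r;
    }
  }
  return Y;
}

// one line-convolution pass along `axis` of a d1 x d2 x d3 buffer,
// half-sample mirror reflection (-1 -> 0, d -> d-1): the resulting
// operator is symmetric and doubly stochastic, so constants and the
// global mean are both preserved exactly.
static void conv_axis(const double *in, double *out, int d1, int d2,
                      int d3, int axis, const double *k, int nk,
                      std::vector<double> &buf) {
  const int r = (nk - 1) / 2;
  const int dax = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
  const int stride = (axis == 1) ? 1 : (axis == 2) ? d1 : d1 * d2;
  const int nline = d1 * d2 * d3 / dax;
  if ((int)buf.size() < dax + 2 * r) buf.resize(dax + 2 * r);
  for (int l = 0; l < nline; ++l) {
    int base;
    if (axis == 1) {
      base = l * d1;
    } else if (axis == 2) {
      const int x = l % d1, z = l / d1;
      base = x + d1 * d2 * z;
    } else {
      base = l;
    }
    for (int i = 0; i < dax; ++i) buf[r + i] = in[base + i * stride];
    for (int m = 0; m < r; ++m) {
      int j = m;                       // position -(m+1) -> m
      buf[r - 1 - m] = buf[r + ((j < dax) ? j : dax - 1)];
      j = dax - 1 - m;                 // position dax+m -> dax-1-m
      buf[dax + r + m] = buf[r + ((j >= 0) ? j : 0)];
    }
    for (int i = 0; i < dax; ++i) {
      double acc = 0.0;
      const double *bp = &buf[i];
      for (int m = 0; m < nk; ++m) acc += k[m] * bp[m];
      out[base + i * stride] = acc;
    }
  }
}

// separable 3D Gaussian smoothing of a 4D (d1, d2, d3, nt) array, one
// scan at a time so the working set stays in cache.
// [[Rcpp::export(name = ".smooth3d")]]
NumericVector smooth3d(NumericVector A, int d1, int d2, int d3, int nt,
                       NumericVector k1, NumericVector k2,
                       NumericVector k3) {
  const R_xlen_t nv = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(no_init(nv * nt));
  std::vector<double> v0(nv), v1(nv), buf;
  const double *a = &A[0];
  double *o = &out[0];
  for (int t = 0; t < nt; ++t) {
    const double *in = a + nv * t;
    double *dst = o + nv * t;
    conv_axis(in, v0.data(), d1, d2, d3, 1, &k1[0], k1.size(), buf);
    conv_axis(v0.data(), v1.data(), d1, d2, d3, 2, &k2[0], k2.size(), buf);
    conv_axis(v1.data(), dst, d1, d2, d3, 3, &k3[0], k3.size(), buf);
  }
  return out;
}

// gather rows idx (1-based) of a 4D array viewed as (nv x ns)
// [[Rcpp::export(name = ".gather_rows")]]
NumericMatrix gather_rows(NumericVector A, int nv, int ns,
                          IntegerVector idx) {
  const int m = idx.size();
  NumericMatrix out(m, ns);
  for (int s = 0; s < ns; ++s) {
    const double *a = &A[0] + (R_xlen_t)nv * s;
    double *o = &out(0, s);
    for (int i = 0; i < m; ++i) o[i] = a[idx[i] - 1];
  }
  return out;
}

// copy of A with rows idx (1-based) replaced by M (m x ns)
// [[Rcpp::export(name = ".scatter_rows")]]
NumericVector scatter_rows(NumericVector A, int nv, IntegerVector idx,
                           NumericMatrix M) {
  NumericVector out = clone(A);
  const int m = idx.size(), ns = M.ncol();
  for (int s = 0; s < ns; ++s) {
    double *o = &out[0] + (R_xlen_t)nv * s;
    const double *src = &M(0, s);
    for (int i = 0; i < m; ++i) o[idx[i] - 1] = src[i];
  }
  return out;
}

// RMS frame-to-frame intensity difference over masked voxels of a 4D
// array viewed as (nv x ns); idx is 1-based.
// [[Rcpp::export(name = ".dvars_series")]]
NumericVector dvars_series(NumericVector A, int nv, int ns,
                           IntegerVector idx) {
  const int m = idx.size();
  NumericVector out(ns);
  const double *a0 = &A[0];
  for (int s = 1; s < ns; ++s) {
    const double *a = a0 + (R_xlen_t)nv * (s - 1);
    const double *b = a0 + (R_xlen_t)nv * s;
    double acc = 0.0;
    for (int i = 0; i < m; ++i) {
      const int v = idx[i] - 1;
      const double d = b[v] - a[v];
      acc += d * d;
    }
    out[s] = std::sqrt(acc / m);
  }
  return out;
}
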