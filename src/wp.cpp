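#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Convolution-decimation with circular (periodic) boundary:
//   out[k] = sum_j f[j] * x[(2k + j) mod n],  k = 0 .. n/2 - 1
static void conv_decim(const double* x, int n, const double* f, int nf,
                       double* out) {
  int half = n / 2;
  for (int k = 0; k < half; ++k) {
    double acc = 0.0;
    int base = 2 * k;
    for (int j = 0; j < nf; ++j) {
      int idx = base + j;
      if (idx >= n) idx -= n * (idx / n);
      acc += f[j] * x[idx];
    }
    out[k] = acc;
  }
}

// Adjoint (inverse) step: x[(2k + j) mod n] += h[j] a[k] + g[j] d[k].
// For orthonormal quadrature filters the adjoint is the exact inverse.
static void conv_merge(const double* a, const double* d, int half,
                       const double* h, const double* g, int nf, double* x) {
  int n = 2 * half;
  std::fill(x, x + n, 0.0);
  for (int k = 0; k < half; ++k) {
    int base = 2 * k;
    for (int j = 0; j < nf; ++j) {
      int idx = base + j;
      if (idx >= n) idx -= n * (idx / n);
      x[idx] += h[j] * a[k] + g[j] * d[k];
    }
  }
}

// Full wavelet-packet tree of a single frame.
// Returns a (depth + 1) x n matrix; row L holds the level-L coefficients,
// node (L, f) occupying columns [f * n/2^L, (f + 1) * n/2^L).
// [[Rcpp::export]]
NumericMatrix cpp_wp_tree(NumericVector x, NumericVector h, NumericVector g,
                          int depth) {
  int n = x.size();
  NumericMatrix out(depth + 1, n);
  std::vector<double> cur(n), child(n);
  for (int i = 0; i < n; ++i) { cur[i] = x[i]; out(0, i) = x[i]; }
  std::vector<double> tmp(n);
  for (int L = 1; L <= depth; ++L) {
    int m = n >> (L - 1);      // parent block length
    int half = m >> 1;
    int nodes = 1 << (L - 1);
    for (int f = 0; f < nodes; ++f) {
      const double* px = cur.data() + f * m;
      conv_decim(px, m, h.begin(), h.size(), child.data() + 2 * f * half);
      conv_decim(px, m, g.begin(), g.size(), child.data() + (2 * f + 1) * half);
    }
    for (int i = 0; i < n; ++i) { out(L, i) = child[i]; cur[i] = child[i]; }
  }
  return out;
}

// One inverse convolution-decimation step.
// [[Rcpp::export]]
NumericVector cpp_wp_merge(NumericVector a, NumericVector d, NumericVector h,
                           NumericVector g) {
  int half = a.size();
  NumericVector x(2 * half);
  conv_merge(a.begin(), d.begin(), half, h.begin(), g.begin(), h.size(),
             x.begin());
  return x;
}

static double mad_sigma(std::vector<double>& v) {
  // median(|v|) / 0.6745 (Gaussian-consistent MAD about zero)
  size_t n = v.size();
  for (size_t i = 0; i < n; ++i) v[i] = std::fabs(v[i]);
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double med = v[mid];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
    med = 0.5 * (med + v[mid - 1]);
  }
  return med / 0.6745;
}

// Batch BAF extraction: for each window (0-based starts into `samples`),
// build the packet tree, derive the universal hard threshold from the
// finest-scale high-pass block (node (1,1)), and record the retained
// (post-threshold) energy of each requested node.
// thr_mode: 0 = none, 1 = universal, 2 = fixed (tau = fixed_tau).
// [[Rcpp::export]]
NumericMatrix cpp_extract_bafs(NumericVector samples, IntegerVector starts,
                               int n_win, NumericVector h, NumericVector g,
                               int depth, IntegerVector node_level,
                               IntegerVector node_f, int thr_mode,
                               double fixed_tau) {
  int nw = starts.size(), nn = node_level.size();
  NumericMatrix out(nw, nn);
  std::vector<double> cur(n_win), child(n_win), sig(n_win);
  int nf = h.size();
  for (int w = 0; w < nw; ++w) {
    int s0 = starts[w];
    for (int i = 0; i < n_win; ++i) cur[i] = samples[s0 + i];
    // store every level's coefficients level-by-level
    std::vector< std::vector<double> > levels(depth + 1);
    levels[0] = cur;
    for (int L = 1; L <= depth; ++L) {
      int m = n_win >> (L - 1);
      int half = m >> 1;
      int nodes = 1 << (L - 1);
      for (int f = 0; f < nodes; ++f) {
        const double* px = cur.data() + f * m;
        conv_decim(px, m, h.begin(), nf, child.data() + 2 * f * half);
        conv_decim(px, m, g.begin(), nf, child.data() + (2 * f + 1) * half);
      }
      levels[L].assign(child.begin(), child.begin() + n_win);
      std::copy(child.begin(), child.begin() + n_win, cur.begin());
    }
    double tau = 0.0;
    if (thr_mode == 1) {
      int half = n_win / 2;
      std::vector<double> d1(levels[1].begin() + half, levels[1].end());
      tau = mad_sigma(d1) * std::sqrt(2.0 * std::log((double)n_win));
    } else if (thr_mode == 2) {
      tau = fixed_tau;
    }
    for (int q = 0; q < nn; ++q) {
      int L = node_level[q], f = node_f[q];
      int m = n_win >> L;
      const double* blk = levels[L].data() + f * m;
      double e = 0.0;
      for (int i = 0; i < m; ++i) {
        double c = blk[i];
        if (std::fabs(c) >= tau) e += c * c;
      }
      out(w, q) = e;
    }
  }
  return out;
}
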