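// Hot paths of the nonlocal denoiser: exhaustive block matching over all
// exemplars and the per-group residual-SVD shrinkage/aggregation sweep.
// Semantics mirror the R-level block_match()/denoise_group()/
// aggregate_groups() exactly (0-based corners, column-major patches,
// ties by row-major scan order); equivalence is asserted in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double patch_ssd(const arma::mat& img, int r1, int c1,
                               int r2, int c2, int p, double best) {
  double acc = 0.0;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < p; ++i) {
      double d = img(r1 + i, c1 + j) - img(r2 + i, c2 + j);
      acc += d * d;
    }
    if (acc > best) return acc;  // early abandon
  }
  return acc;
}

// candidate corner range for a window of `win` pixels centred on the
// exemplar patch, clipped to [0, n - p]
static inline void win_range(int ref, int p, int win, int n, int& lo, int& hi) {
  int half = (win - p) / 2;
  lo = ref - half; if (lo < 0) lo = 0;
  hi = ref - half + (win - p); if (hi > n - p) hi = n - p;
}

// [[Rcpp::export]]
IntegerMatrix cpp_block_match_all(const arma::mat& img,
                                  const IntegerMatrix& exemplars,
                                  int p, int window, int N) {
  const int rows = img.n_rows, cols = img.n_cols;
  const int nex = exemplars.nrow();
  IntegerMatrix out(nex * N, 2);

  std::vector<double> d2;
  std::vector<int> cr, cc, idx;
  for (int e = 0; e < nex; ++e) {
    const int rr = exemplars(e, 0), rc = exemplars(e, 1);
    int rlo, rhi, clo, chi;
    win_range(rr, p, window, rows, rlo, rhi);
    win_range(rc, p, window, cols, clo, chi);
    long ncand = (long)(rhi - rlo + 1) * (chi - clo + 1);
    if (ncand < N) { rlo = 0; rhi = rows - p; clo = 0; chi = cols - p; }
    ncand = (long)(rhi - rlo + 1) * (chi - clo + 1);
    if (ncand < N)
      stop("fewer candidate patches than requested even over the whole image");

    d2.clear(); cr.clear(); cc.clear();
    // row-major scan order (rows outer, cols inner), exemplar excluded
    for (int r = rlo; r <= rhi; ++r)
      for (int c = clo; c <= chi; ++c) {
        if (r == rr && c == rc) continue;
        cr.push_back(r); cc.push_back(c);
        d2.push_back(patch_ssd(img, rr, rc, r, c, p,
                               std::numeric_limits<double>::infinity()));
      }
    const int M = (int)d2.size();
    idx.resize(M);
    for (int i = 0; i < M; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return d2[a] < d2[b]; });
    out(e * N, 0) = rr; out(e * N, 1) = rc;
    for (int j = 1; j < N; ++j) {
      out(e * N + j, 0) = cr[idx[j - 1]];
      out(e * N + j, 1) = cc[idx[j - 1]];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_lsm_denoise_pass(const arma::mat& noisy, const arma::mat& guide,
                               const IntegerMatrix& coords, int N, int p,
                               double sigma2, double alpha, double beta,
                               int inner_iters, bool use_guide) {
  const int rows = noisy.n_rows, cols = noisy.n_cols;
  const int M = p * p;
  const int ngroups = coords.nrow() / N;
  arma::mat acc(rows, cols, arma::fill::zeros);
  arma::mat cnt(rows, cols, arma::fill::zeros);

  arma::mat H(M, N), B(M, N), R(M, N), U, V, out(M, N);
  arma::vec s, sraw, tau;

  for (int g = 0; g < ngroups; ++g) {
    for (int j = 0; j < N; ++j) {
      const int r = coords(g * N + j, 0), c = coords(g * N + j, 1);
      int k = 0;
      for (int cc2 = 0; cc2 < p; ++cc2)
        for (int rr2 = 0; rr2 < p; ++rr2, ++k) {
          H(k, j) = noisy(r + rr2, c + cc2);
          B(k, j) = use_guide ? guide(r + rr2, c + cc2) : 0.0;
        }
    }
    R = H - B;
    if (!arma::svd_econ(U, sraw, V, R))
      stop("SVD failed on a patch-group residual");
    s = sraw;
    const int iters = inner_iters < 1 ? 1 : inner_iters;
    for (int it = 0; it < iters; ++it) {
      tau = (alpha + 1.0) / (beta + arma::abs(s));
      s = arma::clamp(sraw - sigma2 * tau, 0.0, arma::datum::inf);
    }
    out = B + U * arma::diagmat(s) * V.t();

    for (int j = 0; j < N; ++j) {
      const int r = coords(g * N + j, 0), c = coords(g * N + j, 1);
      int k = 0;
      for (int cc2 = 0; cc2 < p; ++cc2)
        for (int rr2 = 0; rr2 < p; ++rr2, ++k) {
          acc(r + rr2, c + cc2) += out(k, j);
          cnt(r + rr2, c + cc2) += 1.0;
        }
    }
  }
  if (cnt.min() <= 0.0)
    stop("aggregation found pixels covered by no patch");
  return acc / cnt;
}
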