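// Fast profiled-REML LRT profile for the genome scan and its permutation
// null distribution.  The model at a position is
//   y = X beta + a + q + e,  a ~ N(0, s2a A), q ~ N(0, s2q P), e ~ N(0, s2e I)
// Writing V = s2e W with W = I + ga A + gq P (variance ratios ga, gq), the
// residual scale profiles out of the restricted likelihood analytically:
//   lR(ga, gq) = -1/2 [ (n-p) log 2pi + (n-p) + (n-p) log(Q/(n-p))
//                       + log|W| + log|X' W^-1 X| ]
// with Q the GLS residual quadratic form.  The null model (no QTL) is the
// one-ratio case, minimized by golden section; the full model by
// Nelder-Mead over (log ga, log gq).  All matrices are block diagonal over
// pedigree connected components, which the caller supplies.
//
// The data live behind an external pointer with preallocated work buffers,
// and each likelihood evaluation goes straight to LAPACK (dpotrf/dtrsm) on
// those buffers; permutations only swap in a new response vector.  This is
// what makes Churchill-Doerge permutation thresholds affordable at full
// REML.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double BIG = 1e10;
const double LCLAMP = 25.0;

// in-place lower Cholesky of a column-major symmetric matrix (lower
// triangle referenced); hand-rolled because the blocks are small and
// per-call overhead dominates library routines at this size
bool chol_ip(double* w, int n) {
  for (int j = 0; j < n; ++j) {
    double d = w[j * n + j];
    for (int k = 0; k < j; ++k) {
      const double l = w[k * n + j];
      d -= l * l;
    }
    if (d <= 0.0 || !std::isfinite(d)) return false;
    const double dj = std::sqrt(d);
    w[j * n + j] = dj;
    for (int i = j + 1; i < n; ++i) {
      double s = w[j * n + i];
      for (int k = 0; k < j; ++k) s -= w[k * n + i] * w[k * n + j];
      w[j * n + i] = s / dj;
    }
  }
  return true;
}

// forward-solve L Z = B in place for m right-hand sides
void trsv_lower(const double* w, int n, double* z, int m) {
  for (int c = 0; c < m; ++c) {
    double* b = z + c * n;
    for (int i = 0; i < n; ++i) {
      double s = b[i];
      for (int j = 0; j < i; ++j) s -= w[j * n + i] * b[j];
      b[i] = s / w[i * n + i];
    }
  }
}

struct Block {
  int n;
  arma::mat A;                  // relationship sub-matrix
  std::vector<arma::mat> P;     // IBD sub-matrix per position
  arma::mat X;                  // fixed-effect rows
  arma::vec y;
  std::vector<int> ix;          // 0-based rows into the full response
  // work buffers
  arma::mat W;                  // n x n
  arma::mat M;                  // n x (p+1), [X y] then L^-1 [X y]
};

struct ScanHandle {
  std::vector<Block> blk;
  int n, p, npos;
  arma::mat G;      // (p+1) x (p+1) accumulator
  arma::mat C;      // p x p copy for factorization
  arma::vec beta;
};

// profiled restricted negative log-likelihood; pos = -1 for the null model
double prof_nll(ScanHandle& h, double lga, double lgq, int pos) {
  if (lga > LCLAMP) lga = LCLAMP;
  if (lga < -LCLAMP) lga = -LCLAMP;
  if (lgq > LCLAMP) lgq = LCLAMP;
  const double ga = std::exp(lga);
  const double gq = (pos >= 0 && lgq >= -LCLAMP) ? std::exp(lgq) : 0.0;
  const int p = h.p;
  const int pc = p + 1;
  double logdetW = 0.0;
  h.G.zeros();
  for (Block& b : h.blk) {
    const int n = b.n;
    double* w = b.W.memptr();
    const double* a = b.A.memptr();
    if (gq > 0.0) {
      const double* q = b.P[pos].memptr();
      for (int i = 0; i < n * n; ++i) w[i] = ga * a[i] + gq * q[i];
    } else {
      for (int i = 0; i < n * n; ++i) w[i] = ga * a[i];
    }
    for (int i = 0; i < n; ++i) w[i * n + i] += 1.0;
    if (!chol_ip(w, n)) return BIG;
    for (int i = 0; i < n; ++i) logdetW += 2.0 * std::log(w[i * n + i]);
    // M = [X y]; solve L M' = M
    std::copy(b.X.memptr(), b.X.memptr() + n * p, b.M.memptr());
    std::copy(b.y.memptr(), b.y.memptr() + n, b.M.memptr() + n * p);
    trsv_lower(w, n, b.M.memptr(), pc);
    // G += M' M (upper triangle is enough)
    const double* m = b.M.memptr();
    for (int j = 0; j < pc; ++j)
      for (int i = 0; i <= j; ++i) {
        double s = 0.0;
        const double* ci = m + i * n;
        const double* cj = m + j * n;
        for (int k = 0; k < n; ++k) s += ci[k] * cj[k];
        h.G(i, j) += s;
      }
  }
  // split G into X'WiX (p x p), X'Wiy, y'Wiy
  for (int j = 0; j < p; ++j)
    for (int i = 0; i <= j; ++i) {
      h.C(i, j) = h.G(i, j);
      h.C(j, i) = h.G(i, j);
    }
  double* c = h.C.memptr();
  if (!chol_ip(c, p)) return BIG;
  double ld2 = 0.0;
  for (int i = 0; i < p; ++i) ld2 += 2.0 * std::log(c[i * p + i]);
  double* bt = h.beta.memptr();
  for (int i = 0; i < p; ++i) bt[i] = h.G(i, p);
  trsv_lower(c, p, bt, 1);
  for (int i = p - 1; i >= 0; --i) {  // back-substitution with L^T
    double s = bt[i];
    for (int j = i + 1; j < p; ++j) s -= c[i * p + j] * bt[j];
    bt[i] = s / c[i * p + i];
  }
  double quad = h.G(p, p);
  for (int i = 0; i < p; ++i) quad -= h.beta[i] * h.G(i, p);
  const int df = h.n - p;
  if (quad <= 1e-300) return BIG;
  return 0.5 * (df * std::log(2.0 * M_PI) + df + df * std::log(quad / df) +
                logdetW + ld2);
}

// golden-section minimum of the null profile over log ga
double golden_null(ScanHandle& h, double& lga_hat) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = -LCLAMP, b = LCLAMP;
  double c = b - gr * (b - a), e = a + gr * (b - a);
  double fc = prof_nll(h, c, 0, -1), fe = prof_nll(h, e, 0, -1);
  for (int it = 0; it < 55; ++it) {
    if (fc < fe) { b = e; e = c; fe = fc; c = b - gr * (b - a);
                   fc = prof_nll(h, c, 0, -1); }
    else { a = c; c = e; fc = fe; e = a + gr * (b - a);
           fe = prof_nll(h, e, 0, -1); }
  }
  lga_hat = (fc < fe) ? c : e;
  return std::min(fc, fe);
}

// compact 2-D Nelder-Mead on (log ga, log gq)
double nm2(ScanHandle& h, int pos, double x0, double y0, double step,
           int maxit, double ftol) {
  double px[3] = {x0, x0 + step, x0};
  double py[3] = {y0, y0, y0 + step};
  double f[3];
  for (int i = 0; i < 3; ++i) f[i] = prof_nll(h, px[i], py[i], pos);
  for (int it = 0; it < maxit; ++it) {
    int hi = 0, lo = 0;
    for (int i = 1; i < 3; ++i) {
      if (f[i] > f[hi]) hi = i;
      if (f[i] < f[lo]) lo = i;
    }
    if (std::fabs(f[hi] - f[lo]) <
        ftol * (std::fabs(f[lo]) + 1e-10) + 1e-12) break;
    double cx = 0, cy = 0;
    for (int i = 0; i < 3; ++i) if (i != hi) { cx += px[i]; cy += py[i]; }
    cx /= 2; cy /= 2;
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double fr = prof_nll(h, rx, ry, pos);
    if (fr < f[lo]) {
      double ex = cx + 2 * (cx - px[hi]), ey = cy + 2 * (cy - py[hi]);
      double fe = prof_nll(h, ex, ey, pos);
      if (fe < fr) { px[hi] = ex; py[hi] = ey; f[hi] = fe; }
      else { px[hi] = rx; py[hi] = ry; f[hi] = fr; }
    } else if (fr < f[hi]) {
      px[hi] = rx; py[hi] = ry; f[hi] = fr;
    } else {
      double kx = cx + 0.5 * (px[hi] - cx), ky = cy + 0.5 * (py[hi] - cy);
      double fk = prof_nll(h, kx, ky, pos);
      if (fk < f[hi]) { px[hi] = kx; py[hi] = ky; f[hi] = fk; }
      else {  // shrink toward the best vertex
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          f[i] = prof_nll(h, px[i], py[i], pos);
        }
      }
    }
  }
  return std::min(std::min(f[0], f[1]), f[2]);
}

}  // namespace

// [[Rcpp::export(name = ".scan_prepare_cpp")]]
SEXP scan_prepare_cpp(const List& blocks, int n, int p, int npos) {
  Rcpp::XPtr<ScanHandle> h(new ScanHandle, true);
  h->n = n; h->p = p; h->npos = npos;
  h->G.set_size(p + 1, p + 1);
  h->C.set_size(p, p);
  h->beta.set_size(p);
  int nb = blocks.size();
  for (int b = 0; b < nb; ++b) {
    List blk = blocks[b];
    Block B;
    IntegerVector ixr = blk["ix"];
    B.n = ixr.size();
    B.ix.resize(B.n);
    for (int i = 0; i < B.n; ++i) B.ix[i] = ixr[i] - 1;
    B.X = as<arma::mat>(blk["X"]);
    B.A = as<arma::mat>(blk["A"]);
    List Ps = blk["P"];
    B.P.reserve(npos);
    for (int k = 0; k < npos; ++k) B.P.push_back(as<arma::mat>(Ps[k]));
    B.y.set_size(B.n);
    B.W.set_size(B.n, B.n);
    B.M.set_size(B.n, p + 1);
    h->blk.push_back(std::move(B));
  }
  return h;
}

// [[Rcpp::export(name = ".ptr_is_null")]]
bool ptr_is_null(SEXP p) {
  return TYPEOF(p) != EXTPTRSXP || R_ExternalPtrAddr(p) == NULL;
}

// [[Rcpp::export(name = ".scan_lrt_cpp")]]
NumericVector scan_lrt_cpp(SEXP handle, const NumericVector& y,
                           bool thorough) {
  Rcpp::XPtr<ScanHandle> h(handle);
  for (Block& b : h->blk)
    for (int i = 0; i < b.n; ++i) b.y[i] = y[b.ix[i]];
  double lga_hat;
  double f0 = golden_null(*h, lga_hat);
  NumericVector lrt(h->npos);
  for (int k = 0; k < h->npos; ++k) {
    double f1 = nm2(*h, k, lga_hat, -10.0, 1.5, thorough ? 250 : 120,
                    thorough ? 1e-10 : 1e-9);
    if (thorough) {
      f1 = std::min(f1, nm2(*h, k, lga_hat, -1.0, 1.5, 250, 1e-10));
      f1 = std::min(f1, nm2(*h, k, 0.0, 0.0, 2.0, 250, 1e-10));
    }
    double l = 2.0 * (f0 - f1);
    lrt[k] = l > 0 ? l : 0.0;
  }
  return lrt;
}
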