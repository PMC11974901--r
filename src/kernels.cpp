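#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded pairwise-complete r^2: out(off-1, j) = r^2 between dosage columns j
// and j+off for off in 1..width-1, computed over entries where both columns
// are observed. Constant columns or fewer than 2 complete pairs give 0.
// [[Rcpp::export]]
NumericMatrix cpp_banded_r2(const IntegerMatrix& d, int width) {
  const int n = d.nrow(), m = d.ncol();
  const int band = std::max(width - 1, 0);
  NumericMatrix out(band, m);
  std::fill(out.begin(), out.end(), NA_REAL);
  const int* dp = INTEGER(d);
  for (int off = 1; off <= band; ++off) {
    for (int j = 0; j + off < m; ++j) {
      const int* x = dp + (R_xlen_t)j * n;
      const int* y = dp + (R_xlen_t)(j + off) * n;
      int nn = 0;
      long sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      for (int i = 0; i < n; ++i) {
        const int xi = x[i], yi = y[i];
        if (xi == NA_INTEGER || yi == NA_INTEGER) continue;
        ++nn;
        sx += xi; sy += yi;
        sxx += xi * xi; syy += yi * yi; sxy += xi * yi;
      }
      double r2 = 0.0;
      if (nn >= 2) {
        const double cov = sxy - (double)sx * sy / nn;
        const double vx = sxx - (double)sx * sx / nn;
        const double vy = syy - (double)sy * sy / nn;
        if (vx > 0 && vy > 0) r2 = cov * cov / (vx * vy);
      }
      out(off - 1, j) = r2;
    }
  }
  return out;
}

// one EM pass for rows of G with F fixed: writes the updated proportions to
// `qout` and returns the log-likelihood at `qin` (both row-major n x K here;
// caller handles layout). Columns of G with missing entries are skipped.
static double em_pass(const int* G, int n, int m, const double* F, int K,
                      const double* qin, double* qout, bool update) {
  double ll = 0.0;
  std::vector<double> acc(K);
  for (int i = 0; i < n; ++i) {
    const double* qi = qin + (size_t)i * K;
    double* qo = qout + (size_t)i * K;
    std::fill(acc.begin(), acc.end(), 0.0);
    int mi = 0;
    for (int j = 0; j < m; ++j) {
      const int g = G[(size_t)j * n + i];
      if (g == NA_INTEGER) continue;
      ++mi;
      const double* fj = F + (size_t)j * K;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += qi[k] * fj[k];
      const double q1 = 1.0 - p;
      ll += (g == 0) ? 2.0 * std::log(q1)
          : (g == 2) ? 2.0 * std::log(p)
                     : std::log(p) + std::log(q1);
      if (update) {
        const double wa = g / p, wb = (2 - g) / q1;
        for (int k = 0; k < K; ++k) {
          acc[k] += qi[k] * (fj[k] * wa + (1.0 - fj[k]) * wb);
        }
      }
    }
    if (update) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += acc[k];
      if (mi > 0 && s > 0) {
        for (int k = 0; k < K; ++k) qo[k] = acc[k] / s;
      } else {
        std::copy(qi, qi + K, qo);
      }
    }
  }
  return ll;
}

// EM for the admixture model over the rows of G with the ancestral
// frequencies F held fixed (the supervised fast path: with one-hot reference
// rows, F is stationary at the observed group frequencies, so only query
// proportions move). Cycles take two EM steps plus a monotonicity-guarded
// squared-extrapolation (SQUAREM-style) step, which repairs the sublinear
// convergence plain EM suffers when proportions approach the simplex
// boundary; a cycle whose extrapolation would lower the likelihood falls
// back to the plain double step, so the recorded log-likelihood trace is
// non-decreasing. The trace holds the likelihood at the start of every
// cycle; convergence is declared when it changes by less than tol.
// [[Rcpp::export]]
List cpp_em_fixed_f(const IntegerMatrix& G, const NumericMatrix& Fmat,
                    const NumericMatrix& Q0, double tol, int max_iter) {
  const int n = G.nrow(), m = G.ncol(), K = Fmat.nrow();
  if (Q0.nrow() != n || Q0.ncol() != K || Fmat.ncol() != m)
    stop("Dimension mismatch in cpp_em_fixed_f.");
  const int* Gp = INTEGER(G);
  // row-major copies: sample-contiguous proportions, SNP-contiguous F
  std::vector<double> F((size_t)m * K), th0((size_t)n * K), th1(th0.size()),
      th2(th0.size()), ex(th0.size()), scratch(th0.size());
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) F[(size_t)j * K + k] = Fmat(k, j);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) th0[(size_t)i * K + k] = Q0(i, k);

  std::vector<double> trace;
  bool converged = false;
  int it = 0;
  double ll_prev = R_NegInf;
  while (true) {
    const double ll0 = em_pass(Gp, n, m, F.data(), K, th0.data(), th1.data(), true);
    if (!R_finite(ll0)) stop("Non-finite log-likelihood at iteration %d.", it);
    trace.push_back(ll0);
    if (it > 0 && std::abs(ll0 - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll0;
    if (it >= max_iter) break;
    ++it;
    const double ll1 = em_pass(Gp, n, m, F.data(), K, th1.data(), th2.data(), true);
    // squared extrapolation from (th0, th1, th2), projected back to the simplex
    double rr = 0.0, vv = 0.0;
    for (size_t t = 0; t < th0.size(); ++t) {
      const double r = th1[t] - th0[t];
      const double v = th2[t] - 2.0 * th1[t] + th0[t];
      rr += r * r;
      vv += v * v;
    }
    bool accepted = false;
    if (vv > 0.0 && rr > 0.0) {
      double alpha = -std::sqrt(rr / vv);
      if (alpha > -1.0) alpha = -1.0;
      // backtrack toward alpha = -1 (the plain double step) if the
      // extrapolation would push a proportion to (or through) zero: exact
      // zeros are absorbing under the multiplicative EM update and can trap
      // a query at a wrong boundary stationary point
      const double floor = 1e-9;
      for (int bt = 0; bt < 5 && !accepted; ++bt) {
        bool feasible = true;
        for (int i = 0; i < n && feasible; ++i) {
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            const size_t t = (size_t)i * K + k;
            const double r = th1[t] - th0[t];
            const double v = th2[t] - 2.0 * th1[t] + th0[t];
            const double val = th0[t] - 2.0 * alpha * r + alpha * alpha * v;
            if (th0[t] > floor && val < floor) { feasible = false; break; }
            ex[t] = (val < 0.0) ? 0.0 : val;
            s += val;
          }
          if (feasible && s > 0.0) {
            for (int k = 0; k < K; ++k) ex[(size_t)i * K + k] /= s;
          } else {
            feasible = false;
          }
        }
        if (feasible) {
          const double ll_ex = em_pass(Gp, n, m, F.data(), K, ex.data(),
                                       scratch.data(), false);
          if (R_finite(ll_ex) && ll_ex >= ll1) { // never move below the EM path
            th0.swap(ex);
            accepted = true;
          }
        }
        if (!accepted) {
          alpha = (alpha - 1.0) / 2.0;
          if (alpha >= -1.0 - 1e-12) break;
        }
      }
    }
    if (!accepted) th0.swap(th2);
  }

  NumericMatrix Q(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = th0[(size_t)i * K + k];
  return List::create(_["Q"] = Q, _["trace"] = wrap(trace),
                      _["converged"] = converged, _["n_iter"] = it);
}
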