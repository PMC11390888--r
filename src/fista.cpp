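// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// FISTA (accelerated proximal gradient with backtracking line search and
// restart-on-increase) for Bernoulli / Poisson GLM negative log-likelihoods
// with element-wise L1 and group L2,1 penalties. The design matrix is held
// in single precision for speed; objectives are accumulated in double and
// the returned solution is double.

static double nll_and_resid(const arma::fmat& X, const arma::fvec& offset,
                            const arma::fvec& y, const arma::fvec& theta,
                            bool bernoulli, arma::fvec& resid) {
  arma::fvec g = offset + X * theta;
  double f = 0.0;
  const int n = g.n_elem;
  for (int i = 0; i < n; ++i) {
    double gi = g[i];
    if (bernoulli) {
      double lse = (gi > 0 ? gi : 0.0) + std::log1p(std::exp(-std::fabs(gi)));
      f += lse - y[i] * gi;
      resid[i] = (float)(1.0 / (1.0 + std::exp(-gi)) - y[i]);
    } else {
      if (gi > 30.0) gi = 30.0;  // guard float overflow during line search
      double e = std::exp(gi);
      f += e - y[i] * gi;
      resid[i] = (float)(e - y[i]);
    }
  }
  return f;
}

static double penalty_value(const arma::fvec& theta, const arma::vec& l1w,
                            const IntegerVector& group, double l21,
                            int ngroups) {
  double p = 0.0;
  for (arma::uword j = 0; j < theta.n_elem; ++j)
    p += l1w[j] * std::fabs((double)theta[j]);
  if (l21 > 0 && ngroups > 0) {
    std::vector<double> gn(ngroups, 0.0);
    for (arma::uword j = 0; j < theta.n_elem; ++j)
      if (group[j] > 0) gn[group[j] - 1] += (double)theta[j] * theta[j];
    for (int g = 0; g < ngroups; ++g) p += l21 * std::sqrt(gn[g]);
  }
  return p;
}

static void prox(arma::fvec& v, double step, const arma::vec& l1w,
                 const IntegerVector& group, double l21, int ngroups) {
  for (arma::uword j = 0; j < v.n_elem; ++j) {
    if (l1w[j] > 0) {
      double thr = step * l1w[j], x = v[j];
      v[j] = (float)(x > thr ? x - thr : (x < -thr ? x + thr : 0.0));
    }
  }
  if (l21 > 0 && ngroups > 0) {
    std::vector<double> gn(ngroups, 0.0);
    for (arma::uword j = 0; j < v.n_elem; ++j)
      if (group[j] > 0) gn[group[j] - 1] += (double)v[j] * v[j];
    for (int g = 0; g < ngroups; ++g) gn[g] = std::sqrt(gn[g]);
    for (arma::uword j = 0; j < v.n_elem; ++j) {
      if (group[j] > 0) {
        double n2 = gn[group[j] - 1];
        double scale = (n2 > step * l21) ? (1.0 - step * l21 / n2) : 0.0;
        v[j] = (float)(v[j] * scale);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_fista_glm(List X_blocks, const arma::vec& offset,
                   const arma::vec& y, std::string family,
                   const arma::vec& l1w, IntegerVector group, double l21,
                   const arma::vec& theta0, int max_iter, double tol,
                   const arma::vec& colscale) {
  const bool bernoulli = (family == "bernoulli");
  // single-precision design assembled from column blocks (the full double
  // design matrix is never materialized), with column scaling (diagonal
  // preconditioning) applied on the fly; an R NULL block contributes an
  // intercept column of ones
  const int nrow = offset.n_elem;
  const int ncol = colscale.n_elem;
  arma::fmat Xf(nrow, ncol);
  {
    float* dst = Xf.memptr();
    int j = 0;
    for (int b = 0; b < X_blocks.size(); ++b) {
      if (Rf_isNull(X_blocks[b])) {
        const float v = (float)(1.0 / colscale[j]);
        float* cd = dst + (R_xlen_t)j * nrow;
        for (int i = 0; i < nrow; ++i) cd[i] = v;
        ++j;
        continue;
      }
      NumericMatrix blk = X_blocks[b];
      if (blk.nrow() != nrow) stop("design block row mismatch");
      const double* src = REAL(blk);
      for (int jb = 0; jb < blk.ncol(); ++jb, ++j) {
        const double inv = 1.0 / colscale[j];
        const double* cs = src + (R_xlen_t)jb * nrow;
        float* cd = dst + (R_xlen_t)j * nrow;
        for (int i = 0; i < nrow; ++i) cd[i] = (float)(cs[i] * inv);
      }
    }
    if (j != ncol) stop("design blocks do not match colscale length");
  }
  arma::fvec off = arma::conv_to<arma::fvec>::from(offset);
  arma::fvec yf = arma::conv_to<arma::fvec>::from(y);
  arma::fvec theta = arma::conv_to<arma::fvec>::from(theta0);
  int ngroups = 0;
  for (int j = 0; j < group.size(); ++j) ngroups = std::max(ngroups, group[j]);

  arma::fvec resid(Xf.n_rows);
  arma::fvec zeta = theta;             // momentum point
  double tk = 1.0;
  double L = 1.0;                      // local Lipschitz estimate
  double f_z = nll_and_resid(Xf, off, yf, zeta, bernoulli, resid);
  double F_prev = f_z + penalty_value(theta, l1w, group, l21, ngroups);
  std::vector<double> trace;
  trace.push_back(F_prev);
  arma::fvec theta_prev = theta;
  int it = 0;
  bool diverged = false;

  for (it = 1; it <= max_iter; ++it) {
    arma::fvec grad = Xf.t() * resid;
    L *= 0.9;  // optimistic step growth
    arma::fvec cand;
    double f_cand = 0.0;
    for (int bt = 0; bt < 60; ++bt) {
      cand = zeta - (float)(1.0 / L) * grad;
      prox(cand, 1.0 / L, l1w, group, l21, ngroups);
      arma::fvec d = cand - zeta;
      double gd = arma::dot(arma::conv_to<arma::vec>::from(grad),
                            arma::conv_to<arma::vec>::from(d));
      double dd = arma::dot(arma::conv_to<arma::vec>::from(d),
                            arma::conv_to<arma::vec>::from(d));
      arma::fvec rtmp(Xf.n_rows);
      f_cand = nll_and_resid(Xf, off, yf, cand, bernoulli, rtmp);
      if (!std::isfinite(f_cand)) { L *= 2.0; continue; }
      if (f_cand <= f_z + gd + 0.5 * L * dd + 1e-7 * std::fabs(f_z)) break;
      L *= 2.0;
      if (L > 1e18) { diverged = true; break; }
    }
    if (diverged) break;
    theta_prev = theta;
    theta = cand;
    double F = f_cand + penalty_value(theta, l1w, group, l21, ngroups);
    if (F > F_prev + 1e-6 * (std::fabs(F_prev) + 1.0)) {
      // restart momentum
      tk = 1.0;
      zeta = theta;
    } else {
      double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
      zeta = theta + (float)((tk - 1.0) / tk1) * (theta - theta_prev);
      tk = tk1;
    }
    f_z = nll_and_resid(Xf, off, yf, zeta, bernoulli, resid);
    trace.push_back(F);
    if (std::fabs(F_prev - F) <= tol * (std::fabs(F) + 1.0) && it > 5) {
      F_prev = F;
      break;
    }
    F_prev = F;
  }
  return List::create(_["theta"] = arma::conv_to<arma::vec>::from(theta),
                      _["objective"] = trace,
                      _["iterations"] = it,
                      _["diverged"] = diverged,
                      _["step_size"] = 1.0 / L);
}
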