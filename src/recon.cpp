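// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-cell temporal-mixing products for the reconstruction likelihood.
// Karr: bins x frames x cells cube (K_i maps frame projections to bin drive).

// drive[i, t] = sum_f Karr(t, f, i) * P(i, f) over bins `bins` (1-based) and
// frames 1..maxf
// [[Rcpp::export]]
arma::mat cpp_drive_from_proj(const arma::cube& Karr, const arma::mat& P,
                              const arma::uvec& bins, int maxf) {
  const int n_cells = Karr.n_slices;
  arma::mat out(n_cells, bins.n_elem);
  for (int i = 0; i < n_cells; ++i) {
    arma::mat Ki = Karr.slice(i).cols(0, maxf - 1);
    arma::vec p = P.row(i).subvec(0, maxf - 1).t();
    arma::vec g = Ki * p;
    for (arma::uword b = 0; b < bins.n_elem; ++b) out(i, b) = g(bins[b] - 1);
  }
  return out;
}

// load[i, f] = sum_{t in bins} Karr(t, f, i) * R(i, t_index) (adjoint pass)
// [[Rcpp::export]]
arma::mat cpp_proj_load(const arma::cube& Karr, const arma::mat& R,
                        const arma::uvec& bins, int maxf) {
  const int n_cells = Karr.n_slices;
  arma::mat out(n_cells, Karr.n_cols, arma::fill::zeros);
  for (int i = 0; i < n_cells; ++i) {
    for (int f = 0; f < maxf; ++f) {
      double acc = 0.0;
      for (arma::uword b = 0; b < bins.n_elem; ++b) {
        acc += Karr(bins[b] - 1, f, i) * R(i, b);
      }
      out(i, f) = acc;
    }
  }
  return out;
}

// particle-filter history drive: gh(i, b, k) = h(i, bins[b]) +
//   sum_{f<=fprev} Karr(bins[b], f, i) * Phist(i, f, k)
// [[Rcpp::export]]
arma::cube cpp_pf_history_drive(const arma::cube& Karr,
                                const arma::cube& Phist,
                                const arma::mat& h, const arma::uvec& bins,
                                int fprev) {
  const int n_cells = Karr.n_slices;
  const int n_part = Phist.n_slices;
  arma::cube out(n_cells, bins.n_elem, n_part);
  for (int k = 0; k < n_part; ++k) {
    for (int i = 0; i < n_cells; ++i) {
      for (arma::uword b = 0; b < bins.n_elem; ++b) {
        double acc = h(i, bins[b] - 1);
        for (int f = 0; f < fprev; ++f) {
          acc += Karr(bins[b] - 1, f, i) * Phist(i, f, k);
        }
        out(i, b, k) = acc;
      }
    }
  }
  return out;
}

// Bernoulli log-likelihood of spikes s (cells x nbins) at drive g
// [[Rcpp::export]]
double cpp_bernoulli_ll(const arma::mat& g, const arma::mat& s) {
  double ll = 0.0;
  for (arma::uword j = 0; j < g.n_elem; ++j) {
    double gi = g[j];
    double lse = (gi > 0 ? gi : 0.0) + std::log1p(std::exp(-std::fabs(gi)));
    ll += s[j] * gi - lse;
  }
  return ll;
}

// root-mean-square of each column (no temporary the size of the input)
// [[Rcpp::export]]
arma::vec cpp_col_rms(const arma::mat& X) {
  arma::vec out(X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    double acc = 0.0;
    const double* c = X.colptr(j);
    for (arma::uword i = 0; i < X.n_rows; ++i) acc += c[i] * c[i];
    out[j] = std::sqrt(acc / X.n_rows);
  }
  return out;
}
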