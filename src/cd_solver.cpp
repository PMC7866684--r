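#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double x, double lambda) {
  if (x > lambda) return x - lambda;
  if (x < -lambda) return x + lambda;
  return 0.0;
}

// Coordinate descent for one ADMM block:
//
//   min_beta  w * ||y - X beta||_2^2 + lambda * ||beta||_1
//             + (rho / 2) * ||beta - a||_2^2
//
// Closed-form coordinate update with soft-thresholding; full sweeps
// alternated with active-set sweeps, warm-started from beta0.
// [[Rcpp::export]]
arma::vec cd_block_solve(const arma::mat& X, const arma::vec& y, double w,
                         double lambda, double rho, const arma::vec& a,
                         arma::vec beta, int max_sweeps, double tol) {
  const arma::uword p = X.n_cols;
  arma::rowvec col_ss = arma::sum(arma::square(X), 0);
  arma::vec r = y - X * beta;                 // residual, kept in sync

  bool full_pass = true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      if (!full_pass && beta[j] == 0.0) continue;
      double denom = 2.0 * w * col_ss[j] + rho;
      if (denom <= 0.0) { beta[j] = 0.0; continue; }
      double grad = 2.0 * w * (arma::dot(X.col(j), r) + col_ss[j] * beta[j]) +
                    rho * a[j];
      double bj = soft_threshold(grad, lambda) / denom;
      double d = bj - beta[j];
      if (d != 0.0) {
        r -= X.col(j) * d;
        beta[j] = bj;
        double rel = std::abs(d);
        if (rel > max_delta) max_delta = rel;
      }
    }
    if (max_delta < tol) {
      if (full_pass) break;       // converged on a full sweep
      full_pass = true;           // active set stable: verify with full pass
    } else {
      full_pass = false;          // iterate on the active set
    }
  }
  return beta;
}

// Consensus ADMM for the coupled sparse block problem:
//
//   min  w1 ||y1 - X1 b1||^2 + w2 ||y2 - X2 b2||^2
//        + lambda1 ||b1||_1 + lambda2 ||b2||_1     s.t. b1 = z, b2 = z
//
// Augmented-Lagrangian splitting with scaled duals u1, u2; the z-update
// is the average of (b_i + u_i).  Returns the block iterates b1, b2
// (not the consensus z), the consensus z, and iteration/residual info.
// [[Rcpp::export]]
List admm_consensus(const arma::mat& X1, const arma::vec& y1,
                    const arma::mat& X2, const arma::vec& y2,
                    double w1, double w2, double lambda1, double lambda2,
                    double rho, arma::vec b1, arma::vec b2,
                    arma::vec z, arma::vec u1, arma::vec u2,
                    int max_admm, double admm_tol,
                    int cd_max_sweeps, double cd_tol,
                    int cd_inner_sweeps) {
  const arma::uword p = X1.n_cols;
  int it = 0;
  double r_norm = 0.0, s_norm = 0.0;
  bool converged = false;

  if (rho <= 0.0) {
    // decoupled: each block is a plain lasso
    arma::vec zero(p, arma::fill::zeros);
    b1 = cd_block_solve(X1, y1, w1, lambda1, 0.0, zero, b1, cd_max_sweeps, cd_tol);
    b2 = cd_block_solve(X2, y2, w2, lambda2, 0.0, zero, b2, cd_max_sweeps, cd_tol);
    z = 0.5 * (b1 + b2);
    converged = true;
    it = 1;
  } else {
    for (it = 1; it <= max_admm; ++it) {
      // inexact block updates: a few warm-started CD sweeps per ADMM
      // iteration are enough (the duals absorb the residual error)
      b1 = cd_block_solve(X1, y1, w1, lambda1, rho, z - u1, b1,
                          cd_inner_sweeps, cd_tol);
      b2 = cd_block_solve(X2, y2, w2, lambda2, rho, z - u2, b2,
                          cd_inner_sweeps, cd_tol);
      arma::vec z_old = z;
      z = 0.5 * (b1 + u1 + b2 + u2);
      u1 += b1 - z;
      u2 += b2 - z;
      r_norm = std::sqrt(arma::accu(arma::square(b1 - z)) +
                         arma::accu(arma::square(b2 - z)));
      s_norm = rho * std::sqrt(2.0 * arma::accu(arma::square(z - z_old)));
      double eps_pri = std::sqrt(2.0 * p) * admm_tol +
        admm_tol * std::max(std::sqrt(arma::accu(arma::square(b1)) +
                                      arma::accu(arma::square(b2))),
                            std::sqrt(2.0 * arma::accu(arma::square(z))));
      double eps_dual = std::sqrt(2.0 * p) * admm_tol +
        admm_tol * rho * std::sqrt(arma::accu(arma::square(u1)) +
                                   arma::accu(arma::square(u2)));
      if (!b1.is_finite() || !b2.is_finite())
        stop("non-finite coefficients at ADMM iteration %d", it);
      if (r_norm < eps_pri && s_norm < eps_dual) { converged = true; break; }
    }
    if (it > max_admm) it = max_admm;
  }

  return List::create(_["beta1"] = b1, _["beta2"] = b2, _["z"] = z,
                      _["u1"] = u1, _["u2"] = u2,
                      _["n_iter"] = it, _["converged"] = converged,
                      _["r_norm"] = r_norm, _["s_norm"] = s_norm);
}
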