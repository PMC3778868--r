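// Core multivariate-normal mixture machinery for multiple-trait
// multiple-interval mapping: mixture log-likelihood, E-step posteriors and
// the ECM conditional-maximization updates (with zero masks and
// effect-sharing groups on the T x s effect matrix B).
//
// Conventions shared with the R level:
//   Y     T x n  phenotypes (traits in rows)
//   P     n x J  prior mixing probabilities p_ij (J = 2^m components)
//   Z     s x J  coded-genotype design (main rows +-1/2, epistatic rows
//                products of main rows); s = 0 and J = 1 for the null model
//   group T x s  integer constraint codes: -1 entry fixed at zero,
//                0 free, g > 0 entries of column b sharing code g share one
//                parameter (used for QTL-by-environment equality fits)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Posteriors Pi and per-subject log-likelihood contributions.
// Returns total loglik; fills Pi (n x J). Pi is used as the working buffer
// for the log-weights to avoid repeated allocation.
static double estep_core(const mat& Y, const mat& P, const mat& Z,
                         const vec& u, const mat& B, const mat& Sigma,
                         mat& Pi) {
  const uword T = Y.n_rows, n = Y.n_cols, J = P.n_cols;
  mat R;
  if (!chol(R, Sigma))
    Rcpp::stop("residual covariance is not positive definite");
  double logdet = 2.0 * accu(log(R.diag()));
  mat Siginv = inv_sympd(Sigma);
  const double cst = -0.5 * (T * LOG2PI + logdet);
  Pi.set_size(n, J);
  // quadratic forms via the expansion (y - m)' S (y - m)
  //   = y'Sy - 2 y'Sm + m'Sm, with one n x J cross product
  mat M(T, J);
  M.each_col() = u;
  if (Z.n_rows > 0) M += B * Z;
  mat SM = Siginv * M;                  // T x J
  rowvec qm = sum(M % SM, 0);           // J
  mat SY = Siginv * Y;                  // T x n
  vec qy = sum(Y % SY, 0).t();          // n
  mat CT = Y.t() * SM;                  // n x J
  for (uword j = 0; j < J; ++j) {
    double* out = Pi.colptr(j);
    const double* pj = P.colptr(j);
    const double* ct = CT.colptr(j);
    const double qmj = qm(j);
    for (uword i = 0; i < n; ++i) {
      double q = qy(i) - 2.0 * ct[i] + qmj;
      out[i] = (pj[i] > 0.0) ? cst - 0.5 * q + std::log(pj[i]) : -datum::inf;
    }
  }
  vec m = max(Pi, 1);
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    if (!std::isfinite(m(i)))
      Rcpp::stop("zero mixture density for a subject (numeric underflow)");
    double s = 0.0;
    for (uword j = 0; j < J; ++j) {
      double e = std::exp(Pi(i, j) - m(i));
      Pi(i, j) = e;
      s += e;
    }
    Pi.row(i) /= s;
    ll += m(i) + std::log(s);
  }
  return ll;
}

// One full set of CM updates (u, Sigma, then B columns) in place.
static void cm_core(const mat& Y, const mat& Z, const imat& group,
                    const mat& Pi, vec& u, mat& B, mat& Sigma) {
  const uword T = Y.n_rows, n = Y.n_cols;
  const uword s = Z.n_rows;
  mat ZP, ZWZ;
  if (s > 0) {
    ZP = Z * Pi.t();                       // s x n
    ZWZ = Z * diagmat(sum(Pi, 0).t()) * Z.t(); // s x s
  }
  // u given current B
  vec ybar = mean(Y, 1);
  if (s > 0) u = ybar - (B * mean(ZP, 1));
  else u = ybar;
  // Sigma given new u, current B
  mat C = Y;
  C.each_col() -= u;
  if (s > 0) {
    mat BZP = B * ZP;                      // T x n
    Sigma = (C * C.t() - C * BZP.t() - BZP * C.t() + B * ZWZ * B.t()) / double(n);
  } else {
    Sigma = (C * C.t()) / double(n);
  }
  Sigma = symmatu(0.5 * (Sigma + Sigma.t()));
  if (s == 0) return;
  // B columns, sequential conditional maximizations
  mat Siginv = inv_sympd(Sigma);
  for (uword b = 0; b < s; ++b) {
    double den = ZWZ(b, b);
    if (den <= 0.0)
      Rcpp::stop("degenerate design: sum_i sum_j Pi_ij Z[b,j]^2 = 0");
    bool plain = true;
    for (uword t = 0; t < T; ++t)
      if (group(t, b) != 0) { plain = false; break; }
    if (plain) {
      // whole-column closed form: B_b <- B_b + N_b / den,
      // N_b = sum_ij Pi T_ij Z_bj at current parameters
      vec Nb = C * ZP.row(b).t() - B * ZWZ.col(b);
      B.col(b) += Nb / den;
    } else {
      // element-wise (or shared-group) coordinate updates
      // free singleton entries first, then shared groups
      ivec g = group.col(b);
      // collect distinct codes >= 0 in order; -1 stays zero
      std::vector<int> codes;
      for (uword t = 0; t < T; ++t) {
        int c = g(t);
        if (c < 0) continue;
        if (c == 0) codes.push_back(-1000 - int(t)); // unique tag per free entry
        else if (std::find(codes.begin(), codes.end(), c) == codes.end())
          codes.push_back(c);
      }
      for (size_t k = 0; k < codes.size(); ++k) {
        vec v(T, fill::zeros);
        if (codes[k] <= -1000) {
          v(uword(-1000 - codes[k])) = 1.0;
        } else {
          for (uword t = 0; t < T; ++t) if (g(t) == codes[k]) v(t) = 1.0;
        }
        vec Nb = C * ZP.row(b).t() - B * ZWZ.col(b); // current full residual sum
        double num = dot(v, Siginv * Nb);
        double dd = as_scalar(v.t() * Siginv * v) * den;
        double delta = num / dd;
        B.col(b) += delta * v;
      }
    }
  }
  // enforce exact zeros on masked entries (guards roundoff)
  for (uword b = 0; b < s; ++b)
    for (uword t = 0; t < T; ++t)
      if (group(t, b) < 0) B(t, b) = 0.0;
}

// [[Rcpp::export(name = ".mix_loglik_cpp")]]
double mix_loglik_cpp(const arma::mat& Y, const arma::mat& P, const arma::mat& Z,
                      const arma::vec& u, const arma::mat& B, const arma::mat& Sigma) {
  mat Pi;
  return estep_core(Y, P, Z, u, B, Sigma, Pi);
}

// [[Rcpp::export(name = ".estep_cpp")]]
Rcpp::List estep_cpp(const arma::mat& Y, const arma::mat& P, const arma::mat& Z,
                     const arma::vec& u, const arma::mat& B, const arma::mat& Sigma) {
  mat Pi;
  double ll = estep_core(Y, P, Z, u, B, Sigma, Pi);
  return Rcpp::List::create(Rcpp::Named("posterior") = Pi,
                            Rcpp::Named("loglik") = ll);
}

// [[Rcpp::export(name = ".cm_step_cpp")]]
Rcpp::List cm_step_cpp(const arma::mat& Y, const arma::mat& Z,
                       const arma::imat& group, const arma::mat& Pi,
                       const arma::vec& u0, const arma::mat& B0,
                       const arma::mat& Sigma0) {
  vec u = u0;
  mat B = B0, Sigma = Sigma0;
  cm_core(Y, Z, group, Pi, u, B, Sigma);
  return Rcpp::List::create(Rcpp::Named("u") = u, Rcpp::Named("B") = B,
                            Rcpp::Named("Sigma") = Sigma);
}

// [[Rcpp::export(name = ".ecm_fit_cpp")]]
Rcpp::List ecm_fit_cpp(const arma::mat& Y, const arma::mat& P, const arma::mat& Z,
                       const arma::imat& group,
                       const arma::vec& u0, const arma::mat& B0,
                       const arma::mat& Sigma0,
                       const double eps, const int maxit, const bool relative,
                       const bool keep_trace) {
  vec u = u0;
  mat B = B0, Sigma = Sigma0, Pi;
  // make the start point feasible: masked entries exactly zero, shared
  // entries equal (their mean), so every CM update is a true conditional
  // maximization from the first iteration
  for (uword b = 0; b < B.n_cols; ++b) {
    for (uword t = 0; t < B.n_rows; ++t)
      if (group(t, b) < 0) B(t, b) = 0.0;
    for (uword t = 0; t < B.n_rows; ++t) {
      int g = group(t, b);
      if (g <= 0) continue;
      double sum = 0.0; int cnt = 0;
      for (uword t2 = 0; t2 < B.n_rows; ++t2)
        if (group(t2, b) == g) { sum += B(t2, b); ++cnt; }
      for (uword t2 = 0; t2 < B.n_rows; ++t2)
        if (group(t2, b) == g) B(t2, b) = sum / cnt;
    }
  }
  std::vector<double> trace;
  double prev = -datum::inf, ll = -datum::inf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    ll = estep_core(Y, P, Z, u, B, Sigma, Pi);
    if (keep_trace) trace.push_back(ll);
    if (it > 1) {
      double denom = relative ? std::fabs(prev) : 1.0;
      if ((ll - prev) < eps * denom) { converged = true; break; }
    }
    prev = ll;
    cm_core(Y, Z, group, Pi, u, B, Sigma);
  }
  if (it > maxit) it = maxit;
  return Rcpp::List::create(
      Rcpp::Named("u") = u, Rcpp::Named("B") = B, Rcpp::Named("Sigma") = Sigma,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("posterior") = Pi);
}
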