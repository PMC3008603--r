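// Cox proportional-hazards partial likelihood: Newton-Raphson fit with
// Efron or Breslow handling of tied event times. Written for the probe
// screen, which runs one small fit per probe over tens of thousands of
// probes and again inside every LOOCV round.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Evaluate log partial likelihood, score vector and observed information
// at beta, on data already sorted by ascending time. Walks the sorted
// samples from the largest time down, accumulating risk-set sums, and
// handles each tied-death block with the Efron correction when requested.
static void cox_eval_sorted(const arma::vec& time, const arma::vec& status,
                            const arma::mat& X, const arma::vec& beta,
                            bool efron,
                            double& loglik, arma::vec& U, arma::mat& I) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  // guard against overflow in exp()
  double eta_max = eta.max();
  arma::vec w = arma::exp(eta - eta_max);

  loglik = 0.0;
  U.zeros(p);
  I.zeros(p, p);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  arma::sword i = (arma::sword)n - 1;
  while (i >= 0) {
    double t = time((arma::uword)i);
    // absorb the whole tied-time block into the risk set
    double S0d = 0.0;
    arma::vec S1d(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);
    double eta_sum = 0.0;
    arma::vec xd_sum(p, arma::fill::zeros);
    arma::uword d = 0;
    arma::sword j = i;
    while (j >= 0 && time((arma::uword)j) == t) {
      arma::uword uj = (arma::uword)j;
      double wj = w(uj);
      arma::rowvec xj = X.row(uj);
      S0 += wj;
      S1 += wj * xj.t();
      S2 += wj * (xj.t() * xj);
      if (status(uj) == 1.0) {
        ++d;
        S0d += wj;
        S1d += wj * xj.t();
        S2d += wj * (xj.t() * xj);
        eta_sum += eta(uj) - eta_max;
        xd_sum += xj.t();
      }
      --j;
    }
    if (d > 0) {
      loglik += eta_sum;
      U += xd_sum;
      if (efron && d > 1) {
        for (arma::uword l = 0; l < d; ++l) {
          double frac = (double)l / (double)d;
          double S0e = S0 - frac * S0d;
          arma::vec S1e = S1 - frac * S1d;
          arma::mat S2e = S2 - frac * S2d;
          loglik -= std::log(S0e);
          U -= S1e / S0e;
          I += S2e / S0e - (S1e * S1e.t()) / (S0e * S0e);
        }
      } else {
        loglik -= (double)d * std::log(S0);
        U -= (double)d * (S1 / S0);
        I += (double)d * (S2 / S0 - (S1 * S1.t()) / (S0 * S0));
      }
    }
    i = j;
  }
}

struct CoxResult {
  arma::vec beta;
  arma::mat imat_inv;   // inverse observed information at beta-hat
  double loglik;
  double loglik0;
  bool converged;
  int iter;
};

static CoxResult cox_newton(const arma::vec& time, const arma::vec& status,
                            const arma::mat& X, bool efron,
                            int max_iter, double tol, double beta_max) {
  const arma::uword p = X.n_cols;
  CoxResult res;
  res.beta = arma::vec(p, arma::fill::zeros);
  res.converged = false;
  res.iter = 0;

  double loglik;
  arma::vec U(p);
  arma::mat I(p, p);
  cox_eval_sorted(time, status, X, res.beta, efron, loglik, U, I);
  res.loglik0 = loglik;

  for (int it = 0; it < max_iter; ++it) {
    res.iter = it + 1;
    arma::vec step;
    bool ok = arma::solve(step, I, U, arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) { res.converged = false; break; }
    // step-halving: require the log partial likelihood not to decrease
    double new_ll = 0.0;
    arma::vec newU(p);
    arma::mat newI(p, p);
    arma::vec newbeta;
    int halves = 0;
    double scale = 1.0;
    for (; halves < 30; ++halves) {
      newbeta = res.beta + scale * step;
      cox_eval_sorted(time, status, X, newbeta, efron, new_ll, newU, newI);
      if (std::isfinite(new_ll) && new_ll >= loglik - 1e-12) break;
      scale *= 0.5;
    }
    if (halves == 30) { res.converged = false; break; }
    double delta = arma::abs(newbeta - res.beta).max();
    res.beta = newbeta;
    loglik = new_ll; U = newU; I = newI;
    if (arma::abs(res.beta).max() > beta_max || !std::isfinite(loglik)) {
      res.converged = false;   // monotone separation / divergence
      break;
    }
    if (delta < tol) { res.converged = true; break; }
  }
  res.loglik = loglik;
  arma::mat Iinv;
  if (!arma::inv_sympd(Iinv, I)) {
    if (!arma::inv(Iinv, I)) {
      Iinv = arma::mat(p, p);
      Iinv.fill(NA_REAL);
      res.converged = false;
    }
  }
  res.imat_inv = Iinv;
  return res;
}

// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(NumericVector time, NumericVector status, NumericMatrix X,
                 bool efron = true, int max_iter = 100, double tol = 1e-9,
                 double beta_max = 20.0) {
  arma::vec t(time.begin(), time.size(), false);
  arma::vec s(status.begin(), status.size(), false);
  arma::mat x(X.begin(), X.nrow(), X.ncol(), false);

  arma::uvec ord = arma::stable_sort_index(t);
  arma::vec ts = t(ord), ss = s(ord);
  arma::mat xs = x.rows(ord);

  CoxResult res = cox_newton(ts, ss, xs, efron, max_iter, tol, beta_max);
  arma::vec se = arma::sqrt(res.imat_inv.diag());
  return List::create(
    _["beta"] = NumericVector(res.beta.begin(), res.beta.end()),
    _["se"] = NumericVector(se.begin(), se.end()),
    _["var"] = wrap(res.imat_inv),
    _["loglik"] = res.loglik,
    _["loglik_null"] = res.loglik0,
    _["converged"] = res.converged,
    _["iter"] = res.iter);
}

// Log partial likelihood, score and information at a fixed beta (used for
// likelihood-ratio and score tests, and to tie the log-rank statistic to
// the Cox score test).
// [[Rcpp::export(name = ".cox_eval_cpp")]]
List cox_eval_cpp(NumericVector time, NumericVector status, NumericMatrix X,
                  NumericVector beta, bool efron = true) {
  arma::vec t(time.begin(), time.size(), false);
  arma::vec s(status.begin(), status.size(), false);
  arma::mat x(X.begin(), X.nrow(), X.ncol(), false);
  arma::vec b(beta.begin(), beta.size(), false);

  arma::uvec ord = arma::stable_sort_index(t);
  arma::vec ts = t(ord), ss = s(ord);
  arma::mat xs = x.rows(ord);

  double ll; arma::vec U(x.n_cols); arma::mat I(x.n_cols, x.n_cols);
  cox_eval_sorted(ts, ss, xs, b, efron, ll, U, I);
  return List::create(_["loglik"] = ll,
                      _["score"] = NumericVector(U.begin(), U.end()),
                      _["information"] = wrap(I));
}

// Probe screen: one Cox fit per probe with the probe's expression prepended
// to a fixed clinical covariate block. Returns the expression term's
// coefficient, standard error and convergence flag for every probe.
// expr: probes x samples (log2, preprocessed); Z: samples x q clinical block.
// [[Rcpp::export(name = ".cox_screen_cpp")]]
List cox_screen_cpp(NumericVector time, NumericVector status,
                    NumericMatrix expr, NumericMatrix Z,
                    bool efron = true, int max_iter = 100, double tol = 1e-9,
                    double beta_max = 20.0) {
  arma::vec t(time.begin(), time.size(), false);
  arma::vec s(status.begin(), status.size(), false);
  arma::mat E(expr.begin(), expr.nrow(), expr.ncol(), false);
  arma::mat z(Z.begin(), Z.nrow(), Z.ncol(), false);

  const arma::uword n = z.n_rows, q = z.n_cols, m = E.n_rows;

  arma::uvec ord = arma::stable_sort_index(t);
  arma::vec ts = t(ord), ss = s(ord);
  arma::mat zs = z.rows(ord);

  arma::mat X(n, q + 1);
  X.cols(1, q) = zs;

  NumericVector beta_out(m), se_out(m);
  LogicalVector conv_out(m);
  for (arma::uword k = 0; k < m; ++k) {
    arma::rowvec ek = E.row(k);
    arma::vec e = ek.t();
    X.col(0) = e(ord);
    // constant probe: no information, mark non-converged
    if (X.col(0).max() - X.col(0).min() < 1e-12) {
      beta_out[k] = NA_REAL; se_out[k] = NA_REAL; conv_out[k] = false;
      continue;
    }
    CoxResult res = cox_newton(ts, ss, X, efron, max_iter, tol, beta_max);
    beta_out[k] = res.beta(0);
    se_out[k] = std::sqrt(res.imat_inv(0, 0));
    conv_out[k] = res.converged;
  }
  return List::create(_["beta"] = beta_out, _["se"] = se_out,
                      _["converged"] = conv_out);
}
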