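// Core numerics for the 2D Gaussian-emission HMM: scaled forward/backward,
// Viterbi decoding, and multi-sequence Baum-Welch. All routines work on a
// list of T_i x 2 coordinate matrices so one model can pool the scanpaths of
// a whole observer group, each sequence restarting from pi.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// T x N matrix of log emission densities. covs is a 2x2xN cube.
static arma::mat log_emission(const arma::mat& obs, const arma::mat& means,
                              const arma::cube& covs) {
  const arma::uword T = obs.n_rows, N = means.n_rows;
  arma::mat logB(T, N);
  for (arma::uword j = 0; j < N; ++j) {
    arma::mat S = covs.slice(j);
    double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
    if (!(det > 0.0))
      stop("emission covariance for state %d is not positive definite", (int)j + 1);
    double inv00 = S(1, 1) / det, inv11 = S(0, 0) / det, inv01 = -S(0, 1) / det;
    double cst = -LOG2PI - 0.5 * std::log(det);
    for (arma::uword t = 0; t < T; ++t) {
      double dx = obs(t, 0) - means(j, 0), dy = obs(t, 1) - means(j, 1);
      double q = inv00 * dx * dx + 2.0 * inv01 * dx * dy + inv11 * dy * dy;
      logB(t, j) = cst - 0.5 * q;
    }
  }
  return logB;
}

// Scaled forward pass. Per-row max of logB is factored out before
// exponentiating, so no underflow occurs for sequences up to T ~ 1e4.
// Returns log-likelihood; optionally fills alpha-hat and the per-step
// shifted emission matrix + scale constants for the backward pass.
static double forward_scaled(const arma::mat& logB, const arma::vec& pi,
                             const arma::mat& A, arma::mat* alpha_out,
                             arma::mat* b_out, arma::vec* c_out) {
  const arma::uword T = logB.n_rows, N = logB.n_cols;
  arma::mat alpha(T, N), b(T, N);
  arma::vec cs(T), m(T);
  for (arma::uword t = 0; t < T; ++t) {
    m(t) = logB.row(t).max();
    b.row(t) = arma::exp(logB.row(t) - m(t));
  }
  arma::rowvec a = pi.t() % b.row(0);
  double c = arma::accu(a);
  if (!(c > 0.0)) stop("numerical degeneracy: zero total emission probability at step 1");
  alpha.row(0) = a / c;
  cs(0) = c;
  double ll = std::log(c) + m(0);
  for (arma::uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * A) % b.row(t);
    c = arma::accu(a);
    if (!(c > 0.0))
      stop("numerical degeneracy: zero total emission probability at step %d", (int)t + 1);
    alpha.row(t) = a / c;
    cs(t) = c;
    ll += std::log(c) + m(t);
  }
  if (alpha_out) *alpha_out = alpha;
  if (b_out) *b_out = b;
  if (c_out) *c_out = cs;
  return ll;
}

// [[Rcpp::export]]
double ghmm_loglik_cpp(List obs_list, arma::vec pi, arma::mat A,
                       arma::mat means, arma::cube covs) {
  double ll = 0.0;
  for (int s = 0; s < obs_list.size(); ++s) {
    arma::mat obs = as<arma::mat>(obs_list[s]);
    ll += forward_scaled(log_emission(obs, means, covs), pi, A,
                         nullptr, nullptr, nullptr);
  }
  return ll;
}

// Smoothed state probabilities for one sequence (forward-backward).
// [[Rcpp::export]]
arma::mat ghmm_posterior_cpp(arma::mat obs, arma::vec pi, arma::mat A,
                             arma::mat means, arma::cube covs) {
  const arma::uword T = obs.n_rows, N = pi.n_elem;
  arma::mat logB = log_emission(obs, means, covs), alpha, b;
  arma::vec cs;
  forward_scaled(logB, pi, A, &alpha, &b, &cs);
  arma::mat beta(T, N, arma::fill::ones);
  for (arma::uword t = T - 1; t-- > 0;)
    beta.row(t) = (A * (b.row(t + 1) % beta.row(t + 1)).t()).t() / cs(t + 1);
  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);
  return gamma;
}

// Most probable state path, 0-based; ties resolved toward the lower index.
// [[Rcpp::export]]
IntegerVector ghmm_viterbi_cpp(arma::mat obs, arma::vec pi, arma::mat A,
                               arma::mat means, arma::cube covs) {
  const arma::uword T = obs.n_rows, N = pi.n_elem;
  arma::mat logB = log_emission(obs, means, covs);
  arma::mat logA = arma::log(A);
  arma::vec logpi = arma::log(pi);
  arma::mat delta(T, N);
  arma::umat psi(T, N, arma::fill::zeros);
  delta.row(0) = logpi.t() + logB.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    for (arma::uword j = 0; j < N; ++j) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword i = 0; i < N; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  arma::uword last = delta.row(T - 1).index_max();
  // index_max returns the first maximum, which is the lowest state index
  path[T - 1] = (int)last;
  for (arma::uword t = T - 1; t-- > 0;) {
    last = psi(t + 1, last);
    path[t] = (int)last;
  }
  return path;
}

// Log joint probability of a given state path (used by tests).
// [[Rcpp::export]]
double ghmm_path_logprob_cpp(arma::mat obs, IntegerVector path, arma::vec pi,
                             arma::mat A, arma::mat means, arma::cube covs) {
  arma::mat logB = log_emission(obs, means, covs);
  double lp = std::log(pi(path[0])) + logB(0, path[0]);
  for (int t = 1; t < path.size(); ++t)
    lp += std::log(A(path[t - 1], path[t])) + logB(t, path[t]);
  return lp;
}

// Multi-sequence Baum-Welch. E-step statistics accumulate across sequences;
// pi is re-estimated from the per-sequence initial posteriors. Diagonal
// covariances unless diagonal = false; per-axis variances floored each
// M-step. The returned trace holds the log-likelihood evaluated at the
// start of every iteration plus a final evaluation of the returned model,
// so it is non-decreasing and its last element matches the model reported.
// [[Rcpp::export]]
List ghmm_em_cpp(List obs_list, arma::vec pi, arma::mat A, arma::mat means,
                 arma::cube covs, int max_iter, double tol, double var_floor,
                 bool diagonal) {
  const arma::uword N = pi.n_elem, S = obs_list.size();
  std::vector<arma::mat> obs(S);
  arma::uword n_obs = 0;
  for (arma::uword s = 0; s < S; ++s) {
    obs[s] = as<arma::mat>(obs_list[s]);
    n_obs += obs[s].n_rows;
  }
  std::vector<double> trace;
  bool converged = false;
  int iter = 0;
  double prev_ll = -arma::datum::inf;
  for (iter = 0; iter < max_iter; ++iter) {
    arma::vec pi_acc(N, arma::fill::zeros), g_all(N, arma::fill::zeros),
        g_trans(N, arma::fill::zeros);
    arma::mat xi_acc(N, N, arma::fill::zeros), mu_acc(N, 2, arma::fill::zeros);
    arma::cube S_acc(2, 2, N, arma::fill::zeros);
    double ll = 0.0;
    // E-step over all sequences
    for (arma::uword s = 0; s < S; ++s) {
      const arma::mat& y = obs[s];
      const arma::uword T = y.n_rows;
      arma::mat logB = log_emission(y, means, covs), alpha, b;
      arma::vec cs;
      ll += forward_scaled(logB, pi, A, &alpha, &b, &cs);
      arma::mat beta(T, N, arma::fill::ones);
      for (arma::uword t = T - 1; t-- > 0;)
        beta.row(t) = (A * (b.row(t + 1) % beta.row(t + 1)).t()).t() / cs(t + 1);
      arma::mat gamma = alpha % beta;
      gamma.each_col() /= arma::sum(gamma, 1);
      pi_acc += gamma.row(0).t();
      for (arma::uword t = 0; t + 1 < T; ++t) {
        arma::mat xi = (alpha.row(t).t() * (b.row(t + 1) % beta.row(t + 1))) % A / cs(t + 1);
        xi_acc += xi;
        g_trans += gamma.row(t).t();
      }
      g_all += arma::sum(gamma, 0).t();
      mu_acc += gamma.t() * y;
      // weighted raw second moments; centred with the new means in the M-step
      for (arma::uword j = 0; j < N; ++j) {
        arma::vec w = gamma.col(j);
        S_acc(0, 0, j) += arma::dot(w, y.col(0) % y.col(0));
        S_acc(0, 1, j) += arma::dot(w, y.col(0) % y.col(1));
        S_acc(1, 1, j) += arma::dot(w, y.col(1) % y.col(1));
      }
    }
    trace.push_back(ll);
    if (iter > 0) {
      double rel = std::fabs(ll - prev_ll) / std::max(1.0, std::fabs(ll));
      if (rel < tol) { converged = true; break; }
    }
    prev_ll = ll;
    // M-step
    if (g_all.min() < 1e-8)
      stop("degenerate fit at iteration %d: a state lost all responsibility", iter + 1);
    pi = pi_acc / arma::accu(pi_acc);
    if (N > 1) {
      A = xi_acc;
      A.each_col() /= arma::sum(A, 1);
    }
    arma::mat new_means = mu_acc;
    new_means.each_col() /= g_all;
    for (arma::uword j = 0; j < N; ++j) {
      double w = g_all(j);
      double mx = new_means(j, 0), my = new_means(j, 1);
      double vxx = S_acc(0, 0, j) / w - mx * mx;
      double vyy = S_acc(1, 1, j) / w - my * my;
      double vxy = S_acc(0, 1, j) / w - mx * my;
      vxx = std::max(vxx, var_floor);
      vyy = std::max(vyy, var_floor);
      if (diagonal) vxy = 0.0;
      else {
        // keep the matrix positive definite after flooring
        double lim = 0.999 * std::sqrt(vxx * vyy);
        if (vxy > lim) vxy = lim;
        if (vxy < -lim) vxy = -lim;
      }
      covs(0, 0, j) = vxx; covs(1, 1, j) = vyy;
      covs(0, 1, j) = vxy; covs(1, 0, j) = vxy;
    }
    means = new_means;
  }
  // final evaluation so the reported log-likelihood matches the model
  double final_ll = 0.0;
  for (arma::uword s = 0; s < S; ++s)
    final_ll += forward_scaled(log_emission(obs[s], means, covs), pi, A,
                               nullptr, nullptr, nullptr);
  trace.push_back(final_ll);
  return List::create(
      _["pi"] = pi, _["A"] = A, _["means"] = means, _["covs"] = covs,
      _["log_likelihood"] = final_ll, _["loglik_trace"] = trace,
      _["n_iterations"] = iter + 1, _["converged"] = converged,
      _["n_observations"] = (int)n_obs);
}
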