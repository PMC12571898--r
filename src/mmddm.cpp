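// Computational core: discretized transition kernels, scaled forward-backward
// over the latent grid, Poisson emission log-likelihoods and their gradients.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

static inline double softplus_cpp(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

static inline double sigmoid_cpp(double x) {
  return x >= 0.0 ? 1.0 / (1.0 + std::exp(-x))
                  : std::exp(x) / (1.0 + std::exp(x));
}

// Gaussian bin probabilities over the grid: interior CDF differences, tails
// to the absorbing states. States ordered [-B, interior..., +B].
static void gauss_row(const arma::vec& edges, double mean, double sd,
                      arma::vec& row) {
  const arma::uword ne = edges.n_elem;
  double prev = norm_cdf((edges[0] - mean) / sd);
  row[0] = prev;
  for (arma::uword j = 1; j < ne; ++j) {
    double cur = norm_cdf((edges[j] - mean) / sd);
    row[j] = cur - prev;
    prev = cur;
  }
  row[ne] = 1.0 - prev;
}

// [[Rcpp::export]]
arma::mat cpp_transition(const arma::vec& centers, const arma::vec& edges,
                         double m, double v, double dt) {
  const arma::uword S = centers.n_elem;
  arma::mat A(S, S, arma::fill::zeros);
  A(0, 0) = 1.0;
  A(S - 1, S - 1) = 1.0;
  const double sd = std::sqrt(dt + v);
  arma::vec row(S);
  for (arma::uword i = 1; i + 1 < S; ++i) {
    gauss_row(edges, centers[i] + m, sd, row);
    A.row(i) = row.t();
  }
  return A;
}

// [[Rcpp::export]]
arma::vec cpp_initial(const arma::vec& edges, double mean, double var) {
  const arma::uword S = edges.n_elem + 1;
  arma::vec p(S);
  gauss_row(edges, mean, std::sqrt(var), p);
  return p;
}

// Emission log-likelihood matrix: states x steps. y is neurons x steps,
// b is neurons x steps (baseline input current). Interior states use wEA,
// the two bound states (first and last) use wDC.
// [[Rcpp::export]]
arma::mat cpp_emission_matrix(const arma::mat& y, const arma::vec& centers,
                              const arma::vec& wEA, const arma::vec& wDC,
                              const arma::mat& b, double dt) {
  const arma::uword S = centers.n_elem, T = y.n_cols, N = y.n_rows;
  arma::mat L(S, T, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    for (arma::uword n = 0; n < N; ++n) {
      const double yy = y(n, t), bb = b(n, t);
      const double lg = std::lgamma(yy + 1.0);
      for (arma::uword s = 0; s < S; ++s) {
        const double w = (s == 0 || s == S - 1) ? wDC[n] : wEA[n];
        double lam = softplus_cpp(w * centers[s] + bb) * dt;
        if (lam < 1e-300) lam = 1e-300;
        L(s, t) += yy * std::log(lam) - lam - lg;
      }
    }
  }
  return L;
}

// Scaled forward (optionally backward) pass. Inputs m, v have one entry per
// step; the step-1 input is folded into the initial distribution by the
// caller (mean, var passed directly). logchoice enters as an additional
// emission factor at the final step. Returns the trial log-likelihood,
// filtered probabilities and (optionally) smoothed probabilities.
// [[Rcpp::export]]
List cpp_trial_fb(const arma::vec& centers, const arma::vec& edges,
                  const arma::vec& m, const arma::vec& v, double dt,
                  double init_mean, double init_var,
                  const arma::mat& logem, const arma::vec& logchoice,
                  bool want_smooth) {
  const arma::uword S = centers.n_elem, T = logem.n_cols;
  // click-free steps (m = 0, v = 0) share one transition matrix
  std::vector<arma::mat> A(T > 1 ? T - 1 : 0);
  arma::mat A0;
  bool haveA0 = false;
  for (arma::uword t = 1; t < T; ++t) {
    if (m[t] == 0.0 && v[t] == 0.0) {
      if (!haveA0) {
        A0 = cpp_transition(centers, edges, 0.0, 0.0, dt);
        haveA0 = true;
      }
      A[t - 1] = A0;
    } else {
      A[t - 1] = cpp_transition(centers, edges, m[t], v[t], dt);
    }
  }
  arma::vec chi = arma::exp(logchoice);
  arma::mat alpha(S, T);
  arma::vec cnorm(T, arma::fill::zeros);
  double ll = 0.0;
  bool floored = false;

  arma::vec a = cpp_initial(edges, init_mean, init_var);
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) a = A[t - 1].t() * a;
    // rescale emission column to avoid underflow
    const double mx = logem.col(t).max();
    a %= arma::exp(logem.col(t) - mx);
    if (t == T - 1) {
      // if the hard choice would annihilate all mass, floor the pre-choice
      // state probabilities at 1e-300 and flag (degenerate-trial policy)
      arma::vec pre = a;
      a %= chi;
      if (!(arma::accu(a) > 0.0)) {
        pre.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
        a = pre % chi;
        floored = true;
      }
    }
    double c = arma::accu(a);
    if (!(c > 0.0)) {
      // total mass annihilated even after flooring
      return List::create(_["loglik"] = R_NegInf,
                          _["filtered"] = alpha,
                          _["smoothed"] = alpha,
                          _["ok"] = false);
    }
    a /= c;
    ll += std::log(c) + mx;
    cnorm[t] = c;
    alpha.col(t) = a;
  }

  arma::mat gamma;
  if (want_smooth) {
    gamma.set_size(S, T);
    arma::vec beta(S, arma::fill::ones);
    gamma.col(T - 1) = alpha.col(T - 1);
    for (arma::uword t = T - 1; t-- > 0;) {
      // fold emission (and choice) of step t+1 into beta, then step back
      arma::vec e = arma::exp(logem.col(t + 1) -  logem.col(t + 1).max());
      if (t + 1 == T - 1) e %= chi;
      arma::vec bt = A[t] * (beta % e / cnorm[t + 1]);
      beta = bt;
      arma::vec g = alpha.col(t) % beta;
      double gs = arma::accu(g);
      gamma.col(t) = gs > 0 ? arma::vec(g / gs) : g;
    }
  }
  return List::create(_["loglik"] = ll, _["filtered"] = alpha,
                      _["smoothed"] = gamma, _["ok"] = true,
                      _["floored"] = floored);
}

// Gradient of the summed Poisson emission log-likelihood with respect to
// wEA, wDC and the per-step baseline input b, weighted by the smoothed state
// posterior gamma (Fisher's identity). Returns per-neuron weight gradients
// and an N x T matrix of baseline-input gradients.
// [[Rcpp::export]]
List cpp_emission_grad(const arma::mat& y, const arma::vec& centers,
                       const arma::vec& wEA, const arma::vec& wDC,
                       const arma::mat& b, double dt,
                       const arma::mat& gamma) {
  const arma::uword S = centers.n_elem, T = y.n_cols, N = y.n_rows;
  arma::vec gEA(N, arma::fill::zeros), gDC(N, arma::fill::zeros);
  arma::mat gb(N, T, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    for (arma::uword n = 0; n < N; ++n) {
      const double yy = y(n, t), bb = b(n, t);
      double acc_b = 0.0, acc_ea = 0.0, acc_dc = 0.0;
      for (arma::uword s = 0; s < S; ++s) {
        const double g = gamma(s, t);
        if (g == 0.0) continue;
        const bool bound = (s == 0 || s == S - 1);
        const double w = bound ? wDC[n] : wEA[n];
        const double eta = w * centers[s] + bb;
        double lam = softplus_cpp(eta);
        if (lam < 1e-12) lam = 1e-12;
        // d/d eta of [y log(lam dt) - lam dt] = (y/lam - dt) * sigmoid(eta)
        const double d = g * (yy / lam - dt) * sigmoid_cpp(eta);
        acc_b += d;
        if (bound) acc_dc += d * centers[s];
        else acc_ea += d * centers[s];
      }
      gb(n, t) += acc_b;
      gEA[n] += acc_ea;
      gDC[n] += acc_dc;
    }
  }
  return List::create(_["gwEA"] = gEA, _["gwDC"] = gDC, _["gb"] = gb);
}
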