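// Joint log posterior and gradient of the hierarchical prospect-theory
// choice model, at the packed state q = (eta[S x 3 column-major], mu[3],
// log sigma[3]) in the NON-CENTERED parameterization: the subject score is
// z_ik = mu_k + sigma_k * eta_ik with eta_ik ~ Normal(0, 1), squashed to
// theta_ik = U_k * Phi(z_ik). Non-centering matters here: a collective
// drift of the cohort along the task's flat lambda-rho-tau likelihood
// ridge is then a move in the three group means alone, which the sampler's
// dense mass matrix can absorb. Mirrors the reference R implementation
// (hbayes_posterior); kept in C++ because Hamiltonian sampling evaluates
// it tens of thousands of times per fit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double log_plogis(double x) {
  // log(1 / (1 + exp(-x))) without overflow
  if (x > 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".hbayes_lp_grad")]]
List hbayes_lp_grad(NumericVector q, NumericVector gain, NumericVector loss,
                    NumericVector sgn, IntegerVector idx, int S,
                    NumericVector U) {
  const int N = gain.size();
  const int D = q.size();
  NumericVector grad(D);

  const double mu1 = q[3 * S], mu2 = q[3 * S + 1], mu3 = q[3 * S + 2];
  const double u1 = q[3 * S + 3], u2 = q[3 * S + 4], u3 = q[3 * S + 5];
  const double s1 = std::exp(u1), s2 = std::exp(u2), s3 = std::exp(u3);

  std::vector<double> lam(S), rho(S), tau(S), phi1(S), phi2(S), phi3(S);
  for (int i = 0; i < S; ++i) {
    double z1 = mu1 + s1 * q[i];
    double z2 = mu2 + s2 * q[S + i];
    double z3 = mu3 + s3 * q[2 * S + i];
    lam[i] = U[0] * R::pnorm(z1, 0.0, 1.0, 1, 0);
    rho[i] = U[1] * R::pnorm(z2, 0.0, 1.0, 1, 0);
    tau[i] = U[2] * R::pnorm(z3, 0.0, 1.0, 1, 0);
    phi1[i] = R::dnorm(z1, 0.0, 1.0, 0);
    phi2[i] = R::dnorm(z2, 0.0, 1.0, 0);
    phi3[i] = R::dnorm(z3, 0.0, 1.0, 0);
  }

  double lp_lik = 0.0;
  std::vector<double> dlam(S, 0.0), drho(S, 0.0), dtau(S, 0.0);
  for (int t = 0; t < N; ++t) {
    const int i = idx[t] - 1;  // 1-based subject index from R
    const double lg = std::log(gain[t]), ll = std::log(loss[t]);
    const double G = std::exp(rho[i] * lg);
    const double L = std::exp(rho[i] * ll);
    const double sv = 0.5 * (G - lam[i] * L);
    const double x = sgn[t] * tau[i] * sv;
    lp_lik += log_plogis(x);
    const double w = sgn[t] / (1.0 + std::exp(x));  // d loglik / d(tau*sv)
    dlam[i] += w * tau[i] * (-0.5) * L;
    drho[i] += w * tau[i] * 0.5 * (G * lg - lam[i] * L * ll);
    dtau[i] += w * sv;
  }

  double lp = lp_lik;
  double g_mu1 = 0, g_mu2 = 0, g_mu3 = 0, g_u1 = 0, g_u2 = 0, g_u3 = 0;
  for (int i = 0; i < S; ++i) {
    const double e1 = q[i], e2 = q[S + i], e3 = q[2 * S + i];
    lp += -(e1 * e1 + e2 * e2 + e3 * e3) / 2;   // eta ~ N(0,1)
    const double w1 = dlam[i] * U[0] * phi1[i];
    const double w2 = drho[i] * U[1] * phi2[i];
    const double w3 = dtau[i] * U[2] * phi3[i];
    grad[i] = w1 * s1 - e1;
    grad[S + i] = w2 * s2 - e2;
    grad[2 * S + i] = w3 * s3 - e3;
    g_mu1 += w1;
    g_mu2 += w2;
    g_mu3 += w3;
    g_u1 += w1 * s1 * e1;
    g_u2 += w2 * s2 * e2;
    g_u3 += w3 * s3 * e3;
  }
  lp += R::dnorm(mu1, 0.0, 1.0, 1) + R::dnorm(mu2, 0.0, 1.0, 1) +
        R::dnorm(mu3, 0.0, 1.0, 1);
  lp += -s1 * s1 / 2 + u1 - s2 * s2 / 2 + u2 - s3 * s3 / 2 + u3;

  grad[3 * S] = g_mu1 - mu1;
  grad[3 * S + 1] = g_mu2 - mu2;
  grad[3 * S + 2] = g_mu3 - mu3;
  grad[3 * S + 3] = g_u1 - s1 * s1 + 1;
  grad[3 * S + 4] = g_u2 - s2 * s2 + 1;
  grad[3 * S + 5] = g_u3 - s3 * s3 + 1;

  return List::create(_["lp"] = lp, _["grad"] = grad);
}
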