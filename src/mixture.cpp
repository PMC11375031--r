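#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of the burst-brightness mixture: one skew-normal
// monomer component (location xi, scale omega, shape alpha) plus Gaussian
// n-mer components whose means are integer multiples of the skew-normal
// mean and whose standard deviation equals the skew-normal sd. w holds the
// k mixture weights (summing to one).
//
// Evaluated in compiled code because the bootstrap refits call it tens of
// thousands of times.
// Analytic gradient of the nll in the optimiser parameterisation
// (xi, log omega, alpha, eta[1..k-1]) with w = softmax(c(eta, 0)).
// Returns c(nll, d/dxi, d/dlog_omega, d/dalpha, d/deta...).
// [[Rcpp::export]]
NumericVector mixture_nll_grad_cpp(NumericVector x, double xi, double omega,
                                   double alpha, NumericVector w,
                                   NumericVector wts) {
  const int k = w.size();
  const int n = x.size();
  NumericVector out(3 + k);  // nll, 3 shape derivs, k-1 eta derivs (+pad)
  if (omega <= 0.0) { out[0] = R_PosInf; return out; }
  const double s2pi = std::sqrt(2.0 / M_PI);
  const double delta = alpha / std::sqrt(1.0 + alpha * alpha);
  const double ddelta = std::pow(1.0 + alpha * alpha, -1.5);
  const double mu1 = xi + omega * delta * s2pi;
  const double v1 = 1.0 - 2.0 * delta * delta / M_PI;
  const double sd1 = omega * std::sqrt(v1);
  if (!(sd1 > 0.0) || !(mu1 > 0.0)) { out[0] = R_PosInf; return out; }
  // chain-rule pieces for the tied oligomer components
  const double dmu1_dxi = 1.0, dmu1_dom = delta * s2pi,
    dmu1_dal = omega * s2pi * ddelta;
  const double dsd1_dom = std::sqrt(v1),
    dsd1_dal = -omega * (2.0 * delta / M_PI) * ddelta / std::sqrt(v1);
  double nll = 0.0, g_xi = 0.0, g_om = 0.0, g_al = 0.0;
  std::vector<double> g_w(k, 0.0);
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - xi) / omega;
    const double phi = R::dnorm(z, 0.0, 1.0, 0);
    const double Phi = R::pnorm(alpha * z, 0.0, 1.0, 1, 0);
    const double phau = R::dnorm(alpha * z, 0.0, 1.0, 0);
    const double f1 = 2.0 / omega * phi * Phi;
    // d f1 / d z, then z's dependence on xi and omega
    const double df1_dz = 2.0 / omega * (-z * phi * Phi + phi * phau * alpha);
    const double df1_dxi = -df1_dz / omega;
    const double df1_dom = -f1 / omega - df1_dz * z / omega;
    const double df1_dal = 2.0 / omega * phi * phau * z;
    double p = w[0] * f1;
    double dp_dxi = w[0] * df1_dxi, dp_dom = w[0] * df1_dom,
      dp_dal = w[0] * df1_dal;
    std::vector<double> f(k); f[0] = f1;
    for (int m = 2; m <= k; ++m) {
      const double fm = R::dnorm(x[i], m * mu1, sd1, 0);
      f[m - 1] = fm;
      const double t = (x[i] - m * mu1) / sd1;
      const double dfm_dmu1 = fm * t / sd1 * m;
      const double dfm_dsd1 = fm * (t * t - 1.0) / sd1;
      p += w[m - 1] * fm;
      dp_dxi += w[m - 1] * dfm_dmu1 * dmu1_dxi;
      dp_dom += w[m - 1] * (dfm_dmu1 * dmu1_dom + dfm_dsd1 * dsd1_dom);
      dp_dal += w[m - 1] * (dfm_dmu1 * dmu1_dal + dfm_dsd1 * dsd1_dal);
    }
    p += 1e-300;
    const double c = wts[i];
    nll -= c * std::log(p);
    g_xi -= c * dp_dxi / p;
    g_om -= c * dp_dom / p;
    g_al -= c * dp_dal / p;
    for (int j = 0; j < k; ++j) g_w[j] -= c * (w[j] * f[j] / p - w[j]);
  }
  out[0] = nll;
  out[1] = g_xi;
  out[2] = g_om * omega;   // d/d log(omega)
  out[3] = g_al;
  for (int j = 0; j + 1 < k; ++j) out[4 + j] = g_w[j];
  return out;
}

// [[Rcpp::export]]
double mixture_nll_cpp(NumericVector x, double xi, double omega,
                       double alpha, NumericVector w,
                       NumericVector wts) {
  const int k = w.size();
  const int n = x.size();
  if (omega <= 0.0) return R_PosInf;
  const double delta = alpha / std::sqrt(1.0 + alpha * alpha);
  const double mu1 = xi + omega * delta * std::sqrt(2.0 / M_PI);
  const double sd1 = omega * std::sqrt(1.0 - 2.0 * delta * delta / M_PI);
  if (!(sd1 > 0.0) || !(mu1 > 0.0)) return R_PosInf;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - xi) / omega;
    double dens = w[0] * 2.0 / omega * R::dnorm(z, 0.0, 1.0, 0) *
      R::pnorm(alpha * z, 0.0, 1.0, 1, 0);
    for (int m = 2; m <= k; ++m) {
      dens += w[m - 1] * R::dnorm(x[i], m * mu1, sd1, 0);
    }
    nll -= wts[i] * std::log(dens + 1e-300);
  }
  return nll;
}
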