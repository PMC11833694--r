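// Gradient-ascent kernels for the elongation-rate Poisson GLM.
//
// Both kernels maximize
//   l = sum_j [ s_j log chi_j - kappa . T_j - lambda chi_j U_j ] + xo_sum
//       - nu1 sum|kappa| - nu2 sum kappa^2
// over kappa, with chi_j = s_j / (lambda U_j) re-optimized analytically each
// iteration. A proposed step that lowers the objective (beyond 1e-9 slack)
// is rejected and the learning rate halved, so the accepted trace is
// monotone. L1 steps use the sgn(0) = 0 subgradient: a coefficient at zero
// moves only if the unpenalized gradient exceeds nu1 in magnitude, and a
// step that would cross zero is clipped to exactly zero.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct StepResult {
  double max_delta;
};

// propose kappa_new from kappa and gradient g (unpenalized part already
// includes the L2 term); returns max |delta|
StepResult l1_step(const std::vector<double>& kappa,
                   const std::vector<double>& g,
                   double lr, double nu1, std::vector<double>& out) {
  double md = 0.0;
  const int F = (int)kappa.size();
  for (int f = 0; f < F; ++f) {
    double k = kappa[f], kn;
    if (nu1 > 0.0) {
      if (k == 0.0) {
        double gs = (g[f] > nu1) ? g[f] - nu1 : ((g[f] < -nu1) ? g[f] + nu1 : 0.0);
        kn = lr * gs;
      } else {
        kn = k + lr * (g[f] - (k > 0 ? nu1 : -nu1));
        if (kn * k < 0.0) kn = 0.0;  // crossing zero is clipped
      }
    } else {
      kn = k + lr * g[f];
    }
    out[f] = kn;
    double d = std::fabs(kn - k);
    if (d > md) md = d;
  }
  return StepResult{md};
}

double penalty_term(const std::vector<double>& kappa, double nu1, double nu2) {
  double p = 0.0;
  for (double k : kappa) p += nu1 * std::fabs(k) + nu2 * k * k;
  return p;
}

}  // namespace

// [[Rcpp::export]]
List glm_ascent_dense_cpp(NumericMatrix Y, IntegerVector gene, NumericVector x,
                          NumericVector offset, NumericVector s_j,
                          NumericVector T_tot, double lambda,
                          double nu1, double nu2, NumericVector kappa0,
                          double lr, double tol, int maxit, double xo_sum) {
  const int n = Y.nrow(), F = Y.ncol(), M = s_j.size();
  std::vector<double> kappa(kappa0.begin(), kappa0.end());
  std::vector<double> prop(F), grad(F);
  std::vector<double> w(n), w2(n), U(M), U2(M), chi(M), chi2(M);
  std::vector<double> trace;
  trace.reserve(1024);

  // evaluate objective (and w, U, chi) at a given kappa
  auto eval = [&](const std::vector<double>& kk, std::vector<double>& ww,
                  std::vector<double>& UU, std::vector<double>& cc) {
    std::fill(UU.begin(), UU.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double q = offset[i];
      for (int f = 0; f < F; ++f) q -= Y(i, f) * kk[f];
      ww[i] = std::exp(q);
      UU[gene[i]] += ww[i];
    }
    double obj = xo_sum;
    for (int j = 0; j < M; ++j) {
      cc[j] = s_j[j] / (lambda * UU[j]);
      obj += s_j[j] * std::log(cc[j]) - lambda * cc[j] * UU[j];
    }
    for (int f = 0; f < F; ++f) obj -= kk[f] * T_tot[f];
    return obj - penalty_term(kk, nu1, nu2);
  };

  double obj = eval(kappa, w, U, chi);
  trace.push_back(obj);
  bool converged = false;
  int it = 0, rejects = 0;
  for (it = 1; it <= maxit; ++it) {
    // gradient at current point: lambda * sum_j chi_j V_j - T (+ L2)
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double a = lambda * chi[gene[i]] * w[i];
      for (int f = 0; f < F; ++f) grad[f] += a * Y(i, f);
    }
    for (int f = 0; f < F; ++f)
      grad[f] += -T_tot[f] - 2.0 * nu2 * kappa[f];
    StepResult st = l1_step(kappa, grad, lr, nu1, prop);
    double obj2 = eval(prop, w2, U2, chi2);
    if (!std::isfinite(obj2) || obj2 < obj - 1e-9) {
      lr *= 0.5;
      if (++rejects > 200 || lr <= 0.0)
        stop("objective is diverging; use a smaller learning rate");
      continue;
    }
    kappa.swap(prop);
    w.swap(w2); U.swap(U2); chi.swap(chi2);
    obj = obj2;
    trace.push_back(obj);
    if (st.max_delta < tol) { converged = true; break; }
  }
  return List::create(_["kappa"] = NumericVector(kappa.begin(), kappa.end()),
                      _["chi"] = NumericVector(chi.begin(), chi.end()),
                      _["U"] = NumericVector(U.begin(), U.end()),
                      _["objective"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = it, _["converged"] = converged,
                      _["lr"] = lr);
}

// [[Rcpp::export]]
List glm_ascent_grouped_cpp(IntegerVector Pi, IntegerVector Pj,
                            NumericVector Px, int G, int F,
                            NumericVector m, NumericVector s,
                            NumericMatrix n_gj, NumericVector o_g,
                            NumericVector s_j, NumericVector T_tot,
                            double lambda, double nu1, double nu2,
                            NumericVector kappa0, double lr, double tol,
                            int maxit, double xo_sum) {
  const int M = s_j.size(), NNZ = Pi.size();
  std::vector<double> kappa(kappa0.begin(), kappa0.end());
  std::vector<double> prop(F), grad(F), ks(F);
  std::vector<double> w(G), w2(G), U(M), U2(M), chi(M), chi2(M);
  std::vector<double> trace;
  trace.reserve(1024);

  auto eval = [&](const std::vector<double>& kk, std::vector<double>& ww,
                  std::vector<double>& UU, std::vector<double>& cc) {
    double c0 = 0.0;
    for (int f = 0; f < F; ++f) { ks[f] = kk[f] / s[f]; c0 += kk[f] * m[f] / s[f]; }
    for (int g = 0; g < G; ++g) ww[g] = c0 + o_g[g];
    for (int t = 0; t < NNZ; ++t) ww[Pi[t]] -= ks[Pj[t]] * Px[t];
    for (int g = 0; g < G; ++g) ww[g] = std::exp(ww[g]);
    double obj = xo_sum;
    for (int j = 0; j < M; ++j) {
      double u = 0.0;
      for (int g = 0; g < G; ++g) u += n_gj(g, j) * ww[g];
      UU[j] = u;
      cc[j] = s_j[j] / (lambda * u);
      obj += s_j[j] * std::log(cc[j]) - lambda * cc[j] * u;
    }
    for (int f = 0; f < F; ++f) obj -= kk[f] * T_tot[f];
    return obj - penalty_term(kk, nu1, nu2);
  };

  std::vector<double> a(G);
  double obj = eval(kappa, w, U, chi);
  trace.push_back(obj);
  bool converged = false;
  int it = 0, rejects = 0;
  for (it = 1; it <= maxit; ++it) {
    // a_g = lambda * w_g * sum_j chi_j n_gj ; gradient from group sums
    for (int g = 0; g < G; ++g) {
      double cw = 0.0;
      for (int j = 0; j < M; ++j) cw += chi[j] * n_gj(g, j);
      a[g] = lambda * w[g] * cw;
    }
    double A = 0.0;
    for (int g = 0; g < G; ++g) A += a[g];
    for (int f = 0; f < F; ++f)
      grad[f] = -m[f] / s[f] * A - T_tot[f] - 2.0 * nu2 * kappa[f];
    for (int t = 0; t < NNZ; ++t)
      grad[Pj[t]] += a[Pi[t]] * Px[t] / s[Pj[t]];
    StepResult st = l1_step(kappa, grad, lr, nu1, prop);
    double obj2 = eval(prop, w2, U2, chi2);
    if (!std::isfinite(obj2) || obj2 < obj - 1e-9) {
      lr *= 0.5;
      if (++rejects > 200 || lr <= 0.0)
        stop("objective is diverging; use a smaller learning rate");
      continue;
    }
    kappa.swap(prop);
    w.swap(w2); U.swap(U2); chi.swap(chi2);
    obj = obj2;
    trace.push_back(obj);
    if (st.max_delta < tol) { converged = true; break; }
  }
  return List::create(_["kappa"] = NumericVector(kappa.begin(), kappa.end()),
                      _["chi"] = NumericVector(chi.begin(), chi.end()),
                      _["U"] = NumericVector(U.begin(), U.end()),
                      _["objective"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = it, _["converged"] = converged,
                      _["lr"] = lr);
}
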