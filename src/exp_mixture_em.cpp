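#include <Rcpp.h>
using namespace Rcpp;

// EM for a K-component exponential mixture on positive data.
// Runs to convergence from a given initialisation; returns parameters,
// per-iteration log-likelihood trace and (optionally) the final
// responsibilities.
//
// The E/M updates are closed form:
//   resp_{ik} ∝ pi_k * lambda_k * exp(-lambda_k * x_i)
//   pi_k  = mean_i resp_{ik}
//   lambda_k = sum_i resp_{ik} / sum_i resp_{ik} x_i
//
// K = 2 takes a specialised path: the responsibility is a logistic
// function of x, needing one exp and one log1p per observation.
// [[Rcpp::export(name = ".exp_mixture_em_cpp")]]
List exp_mixture_em_cpp(NumericVector x, NumericVector pi0,
                        NumericVector lambda0, int max_iter,
                        double tol, bool keep_resp) {
  const int n = x.size();
  const int K = pi0.size();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> lam(lambda0.begin(), lambda0.end());
  std::vector<double> ll_trace;
  ll_trace.reserve(256);
  NumericMatrix resp;
  if (keep_resp) resp = NumericMatrix(n, K);

  double ll_old = R_NegInf;
  int iter = 0;
  if (K == 2) {
    for (iter = 0; iter < max_iter; ++iter) {
      const double c1 = std::log(pi[0]) + std::log(lam[0]);
      const double c2 = std::log(pi[1]) + std::log(lam[1]);
      const double dc = c2 - c1, dl = lam[0] - lam[1];
      double ll = 0.0, s1 = 0.0, sx1 = 0.0, s2 = 0.0, sx2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double t = dc + dl * x[i];      // log w2 - log w1
        double r2;
        if (t > 0) {
          const double e = std::exp(-t);
          r2 = 1.0 / (1.0 + e);
          ll += c2 - lam[1] * x[i] + std::log1p(e);
        } else {
          const double e = std::exp(t);
          r2 = e / (1.0 + e);
          ll += c1 - lam[0] * x[i] + std::log1p(e);
        }
        const double r1 = 1.0 - r2;
        s1 += r1; sx1 += r1 * x[i];
        s2 += r2; sx2 += r2 * x[i];
        if (keep_resp) { resp(i, 0) = r1; resp(i, 1) = r2; }
      }
      ll_trace.push_back(ll);
      bool conv = (iter > 0) &&
        (std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + 1e-300));
      ll_old = ll;
      if (conv) break;
      pi[0] = std::max(s1 / n, 1e-300);
      pi[1] = std::max(s2 / n, 1e-300);
      if (sx1 > 0.0) lam[0] = s1 / sx1;
      if (sx2 > 0.0) lam[1] = s2 / sx2;
    }
  } else {
    std::vector<double> wk(K), ck(K), sk(K), sxk(K);
    for (iter = 0; iter < max_iter; ++iter) {
      for (int k = 0; k < K; ++k)
        ck[k] = std::log(pi[k]) + std::log(lam[k]);
      double ll = 0.0;
      std::fill(sk.begin(), sk.end(), 0.0);
      std::fill(sxk.begin(), sxk.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          wk[k] = ck[k] - lam[k] * x[i];
          if (wk[k] > m) m = wk[k];
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          wk[k] = std::exp(wk[k] - m);
          s += wk[k];
        }
        ll += m + std::log(s);
        for (int k = 0; k < K; ++k) {
          double r = wk[k] / s;
          sk[k] += r;
          sxk[k] += r * x[i];
          if (keep_resp) resp(i, k) = r;
        }
      }
      ll_trace.push_back(ll);
      bool conv = (iter > 0) &&
        (std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + 1e-300));
      ll_old = ll;
      if (conv) break;
      for (int k = 0; k < K; ++k) {
        pi[k] = std::max(sk[k] / n, 1e-300);
        if (sxk[k] > 0.0) lam[k] = sk[k] / sxk[k];
      }
    }
  }

  List out = List::create(
    _["weights"] = NumericVector(pi.begin(), pi.end()),
    _["rates"] = NumericVector(lam.begin(), lam.end()),
    _["loglik"] = ll_old,
    _["trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["iterations"] = (int)ll_trace.size());
  if (keep_resp) out["responsibilities"] = resp;
  return out;
}
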