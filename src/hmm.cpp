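#include <Rcpp.h>
using namespace Rcpp;

// EM for the haplotype-cluster hidden Markov model.
//
// Hidden state: cluster z_j in 1..K along each haplotype.
// Initial distribution: w[0, ].  Transition j-1 -> j: stay with probability
// (1 - rho[j]), else jump to a cluster drawn from w[j, ].  Emission:
// Bernoulli(theta[j, k]) for the 0/1 allele.
//
// Exact M-steps for theta, rho and w keep the log-likelihood monotone.
//
// hap: n x m integer matrix of 0/1 alleles.
// Returns theta (m x K), rho (m), w (m x K), gamma (n x m x K posteriors),
// loglik trace.
List hmm_cluster_em(IntegerMatrix hap, int K,
                    NumericMatrix theta_init, NumericVector rho_init,
                    int max_iter, double tol) {
  const int n = hap.nrow(), m = hap.ncol();
  const double eps = 1e-6;
  NumericMatrix theta(clone(theta_init));
  NumericVector rho(clone(rho_init));
  NumericMatrix w(m, K);
  std::fill(w.begin(), w.end(), 1.0 / K);

  NumericVector gamma(static_cast<R_xlen_t>(n) * m * K);
  gamma.attr("dim") = IntegerVector::create(n, m, K);
  std::vector<double> alpha(static_cast<size_t>(m) * K);
  std::vector<double> beta(static_cast<size_t>(m) * K);
  std::vector<double> scale(m);
  std::vector<double> emis(static_cast<size_t>(m) * K);

  // accumulators for M-step
  std::vector<double> th_num(static_cast<size_t>(m) * K), th_den(static_cast<size_t>(m) * K);
  std::vector<double> jump(static_cast<size_t>(m) * K); // sum_h P(jump to k at j)
  std::vector<double> w1(K);

  NumericVector ll_trace(max_iter);
  double prev_ll = R_NegInf;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    std::fill(th_num.begin(), th_num.end(), 0.0);
    std::fill(th_den.begin(), th_den.end(), 0.0);
    std::fill(jump.begin(), jump.end(), 0.0);
    std::fill(w1.begin(), w1.end(), 0.0);
    double ll = 0.0;

    for (int h = 0; h < n; ++h) {
      // emissions
      for (int j = 0; j < m; ++j) {
        int a = hap(h, j);
        for (int k = 0; k < K; ++k) {
          double t = theta(j, k);
          emis[j * K + k] = a ? t : 1.0 - t;
        }
      }
      // forward (scaled)
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        if (j == 0) {
          for (int k = 0; k < K; ++k) {
            alpha[k] = w(0, k) * emis[k];
            s += alpha[k];
          }
        } else {
          double tot = 0.0;
          for (int k = 0; k < K; ++k) tot += alpha[(j - 1) * K + k];
          for (int k = 0; k < K; ++k) {
            double pred = (1.0 - rho[j]) * alpha[(j - 1) * K + k] +
                          rho[j] * w(j, k) * tot;
            alpha[j * K + k] = pred * emis[j * K + k];
            s += alpha[j * K + k];
          }
        }
        scale[j] = s;
        ll += std::log(s);
        for (int k = 0; k < K; ++k) alpha[j * K + k] /= s;
      }
      // backward (scaled by same constants)
      for (int k = 0; k < K; ++k) beta[(m - 1) * K + k] = 1.0;
      for (int j = m - 2; j >= 0; --j) {
        double mix = 0.0;
        for (int k = 0; k < K; ++k)
          mix += w(j + 1, k) * emis[(j + 1) * K + k] * beta[(j + 1) * K + k];
        for (int k = 0; k < K; ++k) {
          double v = (1.0 - rho[j + 1]) * emis[(j + 1) * K + k] * beta[(j + 1) * K + k] +
                     rho[j + 1] * mix;
          beta[j * K + k] = v / scale[j + 1];
        }
      }
      // posteriors + accumulators
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += alpha[j * K + k] * beta[j * K + k];
        int a = hap(h, j);
        for (int k = 0; k < K; ++k) {
          double g = alpha[j * K + k] * beta[j * K + k] / s;
          gamma[h + static_cast<R_xlen_t>(n) * (j + static_cast<R_xlen_t>(m) * k)] = g;
          th_den[j * K + k] += g;
          if (a) th_num[j * K + k] += g;
          if (j == 0) w1[k] += g;
        }
      }
      // jump posteriors: P(jump at j, z_j = k | data)
      for (int j = 1; j < m; ++j) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) tot += alpha[(j - 1) * K + k];
        for (int k = 0; k < K; ++k) {
          double v = tot * rho[j] * w(j, k) * emis[j * K + k] * beta[j * K + k] /
                     scale[j];
          jump[j * K + k] += v;
        }
      }
    }

    ll_trace[iter] = ll;
    // M-step
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < K; ++k) {
        double t = th_den[j * K + k] > 0 ? th_num[j * K + k] / th_den[j * K + k] : 0.5;
        theta(j, k) = std::min(1.0 - eps, std::max(eps, t));
      }
    double w1s = std::accumulate(w1.begin(), w1.end(), 0.0);
    for (int k = 0; k < K; ++k) w(0, k) = w1[k] / w1s;
    for (int j = 1; j < m; ++j) {
      double js = 0.0;
      for (int k = 0; k < K; ++k) js += jump[j * K + k];
      double r = js / n;
      rho[j] = std::min(1.0 - eps, std::max(eps, r));
      if (js > 0)
        for (int k = 0; k < K; ++k) w(j, k) = jump[j * K + k] / js;
    }

    if (iter > 0 && std::abs(ll - prev_ll) <= tol * std::abs(prev_ll)) {
      ++iter;
      break;
    }
    prev_ll = ll;
  }

  return List::create(_["theta"] = theta, _["rho"] = rho, _["w"] = w,
                      _["gamma"] = gamma,
                      _["loglik"] = ll_trace[std::min(iter, max_iter) - 1],
                      _["loglik_trace"] = ll_trace[Range(0, std::min(iter, max_iter) - 1)],
                      _["n_iter"] = std::min(iter, max_iter));
}

extern "C" SEXP _flockscan_hmm_cluster_em(SEXP hapSEXP, SEXP KSEXP,
                                          SEXP thetaSEXP, SEXP rhoSEXP,
                                          SEXP maxitSEXP, SEXP tolSEXP) {
  BEGIN_RCPP
  Rcpp::RObject out;
  out = Rcpp::wrap(hmm_cluster_em(Rcpp::as<IntegerMatrix>(hapSEXP),
                                  Rcpp::as<int>(KSEXP),
                                  Rcpp::as<NumericMatrix>(thetaSEXP),
                                  Rcpp::as<NumericVector>(rhoSEXP),
                                  Rcpp::as<int>(maxitSEXP),
                                  Rcpp::as<double>(tolSEXP)));
  return out;
  END_RCPP
}

extern "C" SEXP _flockscan_xpehh_scan_core(SEXP, SEXP, SEXP, SEXP, SEXP);
extern "C" SEXP _flockscan_wf_children(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                       SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
  {"_flockscan_hmm_cluster_em", (DL_FUNC) &_flockscan_hmm_cluster_em, 6},
  {"_flockscan_xpehh_scan_core", (DL_FUNC) &_flockscan_xpehh_scan_core, 5},
  {"_flockscan_wf_children", (DL_FUNC) &_flockscan_wf_children, 8},
  {NULL, NULL, 0}
};

extern "C" void R_init_flockscan(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
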