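#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA with symmetric Dirichlet priors.
// docs: list of 0-based word-id integer vectors. Deterministic given
// seed (std::mt19937). Returns final count tables and per-sweep
// diagnostics: the complete-data log-likelihood log p(w, z | alpha,
// beta) up to constants, and a per-token predictive log-likelihood of
// the evaluation documents (heldout if supplied, else the training
// docs) under the current phi and the corpus-level mean topic weights.
// [[Rcpp::export]]
List lda_gibbs_fit(List docs, int V, int K, double alpha, double beta,
                   int nIter, int seed, List heldout) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D);
  long Ntot = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    w[d].assign(v.begin(), v.end());
    Ntot += v.size();
  }
  int E = heldout.size();
  std::vector<std::vector<int>> hw(E);
  for (int e = 0; e < E; ++e) {
    IntegerVector v = heldout[e];
    hw[e].assign(v.begin(), v.end());
  }

  IntegerMatrix nkw(K, V), ndk(D, K);
  IntegerVector nk(K);
  std::vector<std::vector<int>> z(D);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int t = static_cast<int>(unif(rng) * K);
      if (t == K) t = K - 1;
      z[d][i] = t;
      nkw(t, w[d][i])++; ndk(d, t)++; nk[t]++;
    }
  }

  NumericVector traceJoint(nIter), tracePred(nIter);
  std::vector<double> p(K);
  double Vbeta = V * beta;

  for (int iter = 0; iter < nIter; ++iter) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        int wi = w[d][i], t = z[d][i];
        nkw(t, wi)--; ndk(d, t)--; nk[t]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (nkw(k, wi) + beta) / (nk[k] + Vbeta) *
                 (ndk(d, k) + alpha);
          tot += p[k];
        }
        double u = unif(rng) * tot, cum = 0.0;
        int tNew = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += p[k];
          if (u <= cum) { tNew = k; break; }
        }
        z[d][i] = tNew;
        nkw(tNew, wi)++; ndk(d, tNew)++; nk[tNew]++;
      }
    }
    // complete-data log-likelihood log p(w | z) + log p(z), Dirichlet-
    // multinomial form up to additive constants
    double lj = 0.0;
    for (int k = 0; k < K; ++k) {
      for (int v = 0; v < V; ++v)
        lj += std::lgamma(nkw(k, v) + beta);
      lj -= std::lgamma(nk[k] + Vbeta);
    }
    for (int d = 0; d < D; ++d) {
      double nd = 0.0;
      for (int k = 0; k < K; ++k) {
        lj += std::lgamma(ndk(d, k) + alpha);
        nd += ndk(d, k);
      }
      lj -= std::lgamma(nd + K * alpha);
    }
    traceJoint[iter] = lj;

    // predictive per-token log-likelihood under current phi and the
    // corpus-mean topic weights
    std::vector<double> thetaBar(K);
    for (int k = 0; k < K; ++k)
      thetaBar[k] = (nk[k] + alpha) / (Ntot + K * alpha);
    double lp = 0.0;
    long nTok = 0;
    if (E > 0) {
      for (int e = 0; e < E; ++e)
        for (size_t i = 0; i < hw[e].size(); ++i) {
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += thetaBar[k] * (nkw(k, hw[e][i]) + beta) / (nk[k] + Vbeta);
          lp += std::log(s); nTok++;
        }
    } else {
      for (int d = 0; d < D; ++d)
        for (size_t i = 0; i < w[d].size(); ++i) {
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += thetaBar[k] * (nkw(k, w[d][i]) + beta) / (nk[k] + Vbeta);
          lp += std::log(s); nTok++;
        }
    }
    tracePred[iter] = nTok ? lp / nTok : 0.0;
  }

  return List::create(_["nkw"] = nkw, _["ndk"] = ndk, _["nk"] = nk,
                      _["traceJoint"] = traceJoint,
                      _["tracePred"] = tracePred);
}
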