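// CBoW and PV-DM paragraph-vector training with the full-softmax
// objective. The context representation is the concatenation of the 2c
// context word input vectors (offsets -c..-1, +1..+c), plus the
// paragraph vector as a final block in PV-DM mode; out-of-window and
// out-of-vocabulary (-1) context slots contribute a zero pad block and
// receive no update. The objective is the mean over positions of
// log p(target | context) with p given by a softmax over the whole
// vocabulary of scores Wout * h.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec contextVec(const arma::mat& Win, const arma::mat& P,
                            const std::vector<int>& doc, int d, int i,
                            int c, bool pvdm, int dim, int K) {
  arma::vec h(K, arma::fill::zeros);
  int L = doc.size();
  int slot = 0;
  for (int off = -c; off <= c; ++off) {
    if (off == 0) continue;
    int j = i + off;
    if (j >= 0 && j < L && doc[j] >= 0)
      h.subvec(slot * dim, (slot + 1) * dim - 1) = Win.row(doc[j]).t();
    ++slot;
  }
  if (pvdm)
    h.subvec(2 * c * dim, K - 1) = P.row(d).t();
  return h;
}

static double logProb(const arma::mat& Wout, const arma::vec& h,
                      int target, arma::vec& gScores) {
  arma::vec scores = Wout * h;
  double m = scores.max();
  arma::vec ex = arma::exp(scores - m);
  double Z = arma::accu(ex);
  gScores = -ex / Z;          // -p
  gScores[target] += 1.0;     // e_target - p
  return scores[target] - m - std::log(Z);
}

static std::vector<std::vector<int>> asDocs(const List& docs) {
  std::vector<std::vector<int>> out(docs.size());
  for (int d = 0; d < (int)docs.size(); ++d) {
    IntegerVector v = docs[d];
    out[d].assign(v.begin(), v.end());
  }
  return out;
}

// mean log-probability of the corpus under the given parameters
// [[Rcpp::export]]
double emb_objective(const arma::mat& Win, const arma::mat& P,
                     const arma::mat& Wout, List docs, int c, bool pvdm) {
  int dim = Win.n_cols, K = Wout.n_cols;
  auto dd = asDocs(docs);
  double tot = 0.0; long n = 0;
  arma::vec g;
  for (int d = 0; d < (int)dd.size(); ++d)
    for (int i = 0; i < (int)dd[d].size(); ++i) {
      if (dd[d][i] < 0) continue;
      arma::vec h = contextVec(Win, P, dd[d], d, i, c, pvdm, dim, K);
      tot += logProb(Wout, h, dd[d][i], g);
      ++n;
    }
  return n ? tot / n : 0.0;
}

// full-batch gradient of the mean log-probability w.r.t. all parameters
// [[Rcpp::export]]
List emb_gradient(const arma::mat& Win, const arma::mat& P,
                  const arma::mat& Wout, List docs, int c, bool pvdm) {
  int dim = Win.n_cols, K = Wout.n_cols;
  auto dd = asDocs(docs);
  arma::mat gWin(arma::size(Win), arma::fill::zeros);
  arma::mat gP(arma::size(P), arma::fill::zeros);
  arma::mat gWout(arma::size(Wout), arma::fill::zeros);
  long n = 0;
  arma::vec g;
  for (int d = 0; d < (int)dd.size(); ++d)
    for (int i = 0; i < (int)dd[d].size(); ++i) {
      if (dd[d][i] < 0) continue;
      arma::vec h = contextVec(Win, P, dd[d], d, i, c, pvdm, dim, K);
      logProb(Wout, h, dd[d][i], g);
      gWout += g * h.t();
      arma::vec gh = Wout.t() * g;
      int L = dd[d].size(), slot = 0;
      for (int off = -c; off <= c; ++off) {
        if (off == 0) continue;
        int j = i + off;
        if (j >= 0 && j < L && dd[d][j] >= 0)
          gWin.row(dd[d][j]) += gh.subvec(slot * dim, (slot + 1) * dim - 1).t();
        ++slot;
      }
      if (pvdm)
        gP.row(d) += gh.subvec(2 * c * dim, K - 1).t();
      ++n;
    }
  if (n) { gWin /= n; gP /= n; gWout /= n; }
  return List::create(_["wordIn"] = gWin, _["para"] = gP,
                      _["wordOut"] = gWout);
}

// stochastic gradient ascent, one position at a time in document order,
// with linearly decaying learning rate; deterministic given seed (the
// seed drives only the initialisation)
// [[Rcpp::export]]
List emb_train(List docs, int V, int dim, int c, double lr, int nEpochs,
               int seed, bool pvdm) {
  auto dd = asDocs(docs);
  int D = dd.size();
  int K = (2 * c + (pvdm ? 1 : 0)) * dim;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);
  arma::mat Win(V, dim), P(pvdm ? D : 0, dim), Wout(V, K, arma::fill::zeros);
  for (auto& x : Win) x = unif(rng);
  for (auto& x : P) x = unif(rng);

  long total = 0;
  for (auto& doc : dd)
    for (int id : doc) if (id >= 0) ++total;
  total *= nEpochs;
  if (total == 0) stop("corpus has no in-vocabulary tokens");

  NumericVector trace(nEpochs);
  long t = 0;
  arma::vec g;
  for (int ep = 0; ep < nEpochs; ++ep) {
    double sum = 0.0; long n = 0;
    for (int d = 0; d < D; ++d) {
      int L = dd[d].size();
      for (int i = 0; i < L; ++i) {
        if (dd[d][i] < 0) continue;
        double eta = lr * std::max(1e-4, 1.0 - (double)t / total);
        arma::vec h = contextVec(Win, P, dd[d], d, i, c, pvdm, dim, K);
        double lp = logProb(Wout, h, dd[d][i], g);
        if (!std::isfinite(lp))
          stop("embedding training diverged: non-finite objective");
        arma::vec gh = Wout.t() * g;
        Wout += eta * (g * h.t());
        int slot = 0;
        for (int off = -c; off <= c; ++off) {
          if (off == 0) continue;
          int j = i + off;
          if (j >= 0 && j < L && dd[d][j] >= 0)
            Win.row(dd[d][j]) +=
              eta * gh.subvec(slot * dim, (slot + 1) * dim - 1).t();
          ++slot;
        }
        if (pvdm)
          P.row(d) += eta * gh.subvec(2 * c * dim, K - 1).t();
        sum += lp; ++n; ++t;
      }
    }
    trace[ep] = n ? sum / n : 0.0;
  }
  return List::create(_["wordIn"] = Win, _["para"] = P,
                      _["wordOut"] = Wout, _["trace"] = trace);
}

// infer a paragraph vector for a new document with frozen word
// matrices: gradient ascent on the objective w.r.t. the fresh
// paragraph vector only, initialised at zero
// [[Rcpp::export]]
arma::rowvec emb_infer(const arma::mat& Win, const arma::mat& Wout,
                       IntegerVector doc, int c, int nSteps, double lr) {
  int dim = Win.n_cols, K = Wout.n_cols;
  std::vector<int> w(doc.begin(), doc.end());
  arma::mat P(1, dim, arma::fill::zeros);
  int L = w.size();
  arma::vec g;
  for (int s = 0; s < nSteps; ++s) {
    double eta = lr * std::max(1e-4, 1.0 - (double)s / nSteps);
    for (int i = 0; i < L; ++i) {
      if (w[i] < 0) continue;
      arma::vec h = contextVec(Win, P, w, 0, i, c, true, dim, K);
      logProb(Wout, h, w[i], g);
      arma::vec gh = Wout.t() * g;
      P.row(0) += eta * gh.subvec(2 * c * dim, K - 1).t();
    }
  }
  return P.row(0);
}
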