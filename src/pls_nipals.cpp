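#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// NIPALS PLS1 on mean-centred data. Fills B (p x ncomp) so that column a
// holds the regression vector using components 1..a+1. Deflation can exhaust
// X before ncomp components are extracted; remaining columns repeat the last
// valid coefficient vector so cross-validation curves are flat past the
// effective rank. Returns the number of components actually extracted.
static int nipals(const arma::mat& Xc, const arma::vec& yc, int ncomp,
                  arma::mat& B, arma::mat& W, arma::mat& P, arma::mat& T,
                  arma::vec& q) {
  const int n = Xc.n_rows, p = Xc.n_cols;
  int A = std::min(ncomp, std::min(n - 1, p));
  arma::mat X(Xc);
  B.zeros(p, ncomp);
  W.zeros(p, std::max(A, 1));
  P.zeros(p, std::max(A, 1));
  T.zeros(n, std::max(A, 1));
  q.zeros(std::max(A, 1));
  int used = 0;
  for (int a = 0; a < A; ++a) {
    arma::vec w = X.t() * yc;
    double wn = arma::norm(w, 2);
    if (wn < 1e-12) break;
    w /= wn;
    arma::vec t = X * w;
    double tt = arma::dot(t, t);
    if (tt < 1e-24) break;
    arma::vec pv = (X.t() * t) / tt;
    double qa = arma::dot(yc, t) / tt;
    X -= t * pv.t();
    W.col(a) = w;
    P.col(a) = pv;
    T.col(a) = t;
    q(a) = qa;
    arma::vec r;
    if (!arma::solve(r, P.cols(0, a).t() * W.cols(0, a), q.subvec(0, a),
                     arma::solve_opts::no_approx)) {
      break;
    }
    B.col(a) = W.cols(0, a) * r;
    used = a + 1;
  }
  for (int a = used; a < ncomp; ++a) {
    if (used > 0)
      B.col(a) = B.col(used - 1);
  }
  return used;
}

// [[Rcpp::export]]
List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int ncomp) {
  arma::rowvec xm = arma::mean(X, 0);
  double ym = arma::mean(y);
  arma::mat Xc = X.each_row() - xm;
  arma::vec yc = y - ym;
  arma::mat B, W, P, T;
  arma::vec q;
  int used = nipals(Xc, yc, ncomp, B, W, P, T, q);
  return List::create(_["coef"] = B, _["weights"] = W, _["loadings"] = P,
                      _["scores"] = T, _["q"] = q, _["x_mean"] = xm,
                      _["y_mean"] = ym, _["n_used"] = used);
}

// Sum of squared held-out errors per component count, refitting on each
// training fold. fold holds 1-based fold ids.
static arma::vec cv_press(const arma::mat& X, const arma::vec& y, int ncomp,
                          const arma::ivec& fold) {
  int K = fold.max();
  arma::vec press(ncomp, arma::fill::zeros);
  arma::mat B, W, P, T;
  arma::vec q;
  for (int k = 1; k <= K; ++k) {
    arma::uvec te = arma::find(fold == k);
    arma::uvec tr = arma::find(fold != k);
    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    arma::rowvec xm = arma::mean(Xtr, 0);
    double ym = arma::mean(ytr);
    arma::mat Xc = Xtr.each_row() - xm;
    arma::vec yc = ytr - ym;
    nipals(Xc, yc, ncomp, B, W, P, T, q);
    arma::mat Xte = X.rows(te);
    Xte.each_row() -= xm;
    arma::mat pred = Xte * B;
    pred += ym;
    arma::vec yte = y.elem(te);
    for (int a = 0; a < ncomp; ++a) {
      arma::vec e = pred.col(a) - yte;
      press(a) += arma::dot(e, e);
    }
  }
  return press;
}

// [[Rcpp::export]]
arma::vec cpp_pls_cv_press(const arma::mat& X, const arma::vec& y, int ncomp,
                           const arma::ivec& fold) {
  return cv_press(X, y, ncomp, fold);
}

// Evaluate every interval combination: for each, cross-validate PLS over
// 1..max_pc components on the concatenated channels and keep the best
// (lowest RMSECV; ties to the smaller component count). start/end are
// 1-based inclusive channel bounds per interval; combos holds 1-based
// interval index sets.
// [[Rcpp::export]]
List cpp_sipls_eval(const arma::mat& X, const arma::vec& y,
                    const IntegerVector& start, const IntegerVector& end,
                    const List& combos, int max_pc, const arma::ivec& fold) {
  const int nc = combos.size();
  NumericVector best_rmsecv(nc);
  IntegerVector best_ncomp(nc);
  const double n = X.n_rows;
  for (int i = 0; i < nc; ++i) {
    if (i % 256 == 0)
      Rcpp::checkUserInterrupt();
    IntegerVector iv = combos[i];
    int tot = 0;
    for (int j = 0; j < iv.size(); ++j)
      tot += end[iv[j] - 1] - start[iv[j] - 1] + 1;
    arma::uvec ch(tot);
    int pos = 0;
    for (int j = 0; j < iv.size(); ++j)
      for (int c = start[iv[j] - 1]; c <= end[iv[j] - 1]; ++c)
        ch(pos++) = c - 1;
    arma::mat Xs = X.cols(ch);
    arma::vec press = cv_press(Xs, y, max_pc, fold);
    int besta = 0;
    double bestv = press(0);
    for (int a = 1; a < max_pc; ++a) {
      if (press(a) < bestv) {
        bestv = press(a);
        besta = a;
      }
    }
    best_rmsecv[i] = std::sqrt(bestv / n);
    best_ncomp[i] = besta + 1;
  }
  return List::create(_["rmsecv"] = best_rmsecv,
                      _["n_components"] = best_ncomp);
}
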