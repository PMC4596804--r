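// Cross-validated linear-discriminant misclassification counts.
//
// The wrapper sequential forward selection evaluates a repeated 10-fold CV
// error for every candidate feature at every greedy step, i.e. ~1e5 small
// LDA fits per pipeline run. Per (repeat, fold) the class means and the
// full pooled within-class scatter over ALL features are precomputed once;
// evaluating a candidate subset is then a small submatrix solve. Fold
// assignments are generated (seeded, stratified) on the R side and passed
// in, so all randomness is owned by R's RNG. Errors are exchanged as
// integer misclassification counts so ties are exact.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct FoldStats {
  int repeat_idx;
  uvec test_rows;
  mat M;     // k x p training class means
  mat S;     // p x p pooled within-class covariance (ntr - k divisor)
};

// y is 1..k; folds is n x repeats with entries 1..nfolds.
static std::vector<FoldStats> precompute(const mat& X, const ivec& y,
                                         int k, const imat& folds) {
  const int n = X.n_rows, p = X.n_cols, R = folds.n_cols;
  std::vector<FoldStats> out;
  for (int r = 0; r < R; ++r) {
    const int nf = folds.col(r).max();
    for (int f = 1; f <= nf; ++f) {
      uvec tr = find(folds.col(r) != f);
      uvec te = find(folds.col(r) == f);
      if (te.n_elem == 0) continue;
      mat M(k, p, fill::zeros);
      vec cnt(k, fill::zeros);
      for (uword i = 0; i < tr.n_elem; ++i) {
        const int c = y(tr(i)) - 1;
        M.row(c) += X.row(tr(i));
        cnt(c) += 1.0;
      }
      for (int c = 0; c < k; ++c) M.row(c) /= cnt(c);
      mat S(p, p, fill::zeros);
      for (uword i = 0; i < tr.n_elem; ++i) {
        const rowvec d = X.row(tr(i)) - M.row(y(tr(i)) - 1);
        S += d.t() * d;
      }
      S /= (double)(tr.n_elem - k);
      out.push_back(FoldStats{r, te, std::move(M), std::move(S)});
    }
  }
  (void)n;
  return out;
}

// Equal-prior linear classifier on the feature subset `cols`; adds each
// fold's misclassification count to perRepeat.
static void eval_counts(const std::vector<FoldStats>& fs, const mat& X,
                        const ivec& y, int k, const uvec& cols,
                        ivec& perRepeat) {
  for (const FoldStats& st : fs) {
    const mat Msub = st.M.cols(cols);           // k x q
    const mat Ssub = st.S(cols, cols);          // q x q
    mat W;
    if (!solve(W, Ssub, Msub.t(),
               solve_opts::no_approx + solve_opts::likely_sympd))
      W = pinv(Ssub) * Msub.t();
    vec c0(k);
    for (int c = 0; c < k; ++c) c0(c) = -0.5 * dot(Msub.row(c), W.col(c));
    for (uword i = 0; i < st.test_rows.n_elem; ++i) {
      const uword row = st.test_rows(i);
      vec x(cols.n_elem);
      for (uword j = 0; j < cols.n_elem; ++j) x(j) = X(row, cols(j));
      vec sc = W.t() * x + c0;
      uword best = sc.index_max();   // first max on ties: deterministic
      if ((int)best != y(row) - 1) perRepeat(st.repeat_idx) += 1;
    }
  }
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_cv_counts(const arma::mat& X,
                                  const arma::ivec& y, int k,
                                  const arma::uvec& cols1,
                                  const arma::imat& folds) {
  std::vector<FoldStats> fs = precompute(X, y, k, folds);
  ivec perRepeat(folds.n_cols, fill::zeros);
  eval_counts(fs, X, y, k, cols1 - 1, perRepeat);
  return Rcpp::wrap(perRepeat);
}

// Greedy sequential forward selection: starting from the empty set (whose
// error is that of the majority-class rule), add the candidate with the
// lowest CV misclassification count while the count strictly decreases.
// Ties go to the smallest column index.
// [[Rcpp::export]]
Rcpp::List cpp_sfs(const arma::mat& X, const arma::ivec& y, int k,
                   const arma::imat& folds, int max_features) {
  const int n = X.n_rows, p = X.n_cols, R = folds.n_cols;
  std::vector<FoldStats> fs = precompute(X, y, k, folds);

  ivec classCnt(k, fill::zeros);
  for (int i = 0; i < n; ++i) classCnt(y(i) - 1) += 1;
  int bestCount = (n - classCnt.max()) * R;

  std::vector<uword> selected;
  std::vector<double> trace;
  std::vector<bool> used(p, false);

  while ((int)selected.size() < max_features) {
    int bestJ = -1;
    int roundBest = bestCount;
    uvec cols(selected.size() + 1);
    for (size_t s = 0; s < selected.size(); ++s) cols(s) = selected[s];
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      cols(selected.size()) = (uword)j;
      ivec perRepeat(R, fill::zeros);
      eval_counts(fs, X, y, k, cols, perRepeat);
      const int c = (int)accu(perRepeat);
      if (c < roundBest) { roundBest = c; bestJ = j; }
    }
    if (bestJ < 0) break;
    used[bestJ] = true;
    selected.push_back((uword)bestJ);
    bestCount = roundBest;
    trace.push_back((double)roundBest / (double)(n * R));
  }

  Rcpp::IntegerVector sel(selected.size());
  for (size_t s = 0; s < selected.size(); ++s) sel[s] = (int)selected[s] + 1;
  return Rcpp::List::create(Rcpp::Named("selected") = sel,
                            Rcpp::Named("errorTrace") = Rcpp::wrap(trace));
}
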