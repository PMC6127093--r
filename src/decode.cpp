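// Per-timepoint multivariate decoding backend.
//
// The hot loop of the pipeline: an L2-regularized logistic classifier is
// refit for every (timepoint, fold) pair on z-standardized channel features
// (standardization estimated on the training fold only), and out-of-fold
// class probabilities are pooled into per-timepoint ROC-AUC values.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Midrank Mann-Whitney AUC of scores for labels (0/1).
static double auc_rank(const vec &scores, const uvec &y) {
  const uword n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double mid = 0.5 * ((i + 1) + (j + 1));
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = mid;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return datum::nan;
  double rank_sum = 0;
  for (uword t = 0; t < n; ++t) if (y(t) == 1) rank_sum += ranks(t);
  return (rank_sum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// Ridge logistic fit by IRLS on standardized features. X: n x p (already
// standardized, no intercept column). Returns (p+1) vector: intercept first.
static vec fit_ridge_logistic(const mat &X, const vec &y, double lambda,
                              int max_iter = 50, double tol = 1e-8) {
  const uword n = X.n_rows, p = X.n_cols;
  vec beta(p + 1, fill::zeros);
  mat Xi(n, p + 1);
  Xi.col(0).ones();
  Xi.cols(1, p) = X;
  vec pen(p + 1, fill::value(lambda));
  pen(0) = 0.0;  // intercept unpenalized
  for (int it = 0; it < max_iter; ++it) {
    vec eta = Xi * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    vec grad = Xi.t() * (y - mu) - pen % beta;
    mat H = Xi.t() * (Xi.each_col() % w);
    H.diag() += pen;
    vec step;
    if (!solve(step, H, grad, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-6;
      step = solve(H, grad);
    }
    beta += step;
    if (norm(step, "inf") < tol) break;
  }
  return beta;
}

// Standardization parameters from the training rows of one timepoint.
static void train_scaler(const mat &Xt, const uvec &tr, vec &mu, vec &sd) {
  mat Xtr = Xt.rows(tr);
  mu = mean(Xtr, 0).t();
  sd = stddev(Xtr, 0, 0).t();
  sd.transform([](double v) { return v > 0 ? v : 1.0; });
}

// data: trials x channels x samples cube (passed flattened with dims).
// folds: 1..k test-fold id per trial. y: 0/1 labels.
// Returns list(auc = vector over samples, prob = trials x samples
// out-of-fold probabilities).
// [[Rcpp::export]]
Rcpp::List cpp_decode_timecourse(Rcpp::NumericVector data_flat,
                                 Rcpp::IntegerVector dims,
                                 Rcpp::IntegerVector folds,
                                 Rcpp::IntegerVector labels,
                                 double lambda) {
  const uword n_trial = dims[0], n_chan = dims[1], n_time = dims[2];
  cube D(data_flat.begin(), n_trial, n_chan, n_time, false);
  uvec y = conv_to<uvec>::from(
      Rcpp::as<std::vector<int>>(labels));
  ivec fid = conv_to<ivec>::from(Rcpp::as<std::vector<int>>(folds));
  int k = fid.max();
  vec yd = conv_to<vec>::from(y);

  vec auc(n_time);
  mat prob(n_trial, n_time);
  for (uword t = 0; t < n_time; ++t) {
    mat Xt = D.slice(t);  // trials x channels
    vec oof(n_trial);
    for (int f = 1; f <= k; ++f) {
      uvec te = find(fid == f);
      uvec tr = find(fid != f);
      vec mu, sd;
      train_scaler(Xt, tr, mu, sd);
      mat Xtr = Xt.rows(tr);
      Xtr.each_row() -= mu.t();
      Xtr.each_row() /= sd.t();
      vec beta = fit_ridge_logistic(Xtr, yd(tr), lambda);
      mat Xte = Xt.rows(te);
      Xte.each_row() -= mu.t();
      Xte.each_row() /= sd.t();
      vec eta = beta(0) + Xte * beta.subvec(1, n_chan);
      oof(te) = 1.0 / (1.0 + exp(-eta));
    }
    prob.col(t) = oof;
    auc(t) = auc_rank(oof, y);
  }
  return Rcpp::List::create(Rcpp::Named("auc") = auc,
                            Rcpp::Named("prob") = prob);
}

// Temporal generalization: same folds for all (train, test) time pairs;
// entry (t, t2) = AUC of out-of-fold probabilities of the model trained at
// t applied to features at t2 (standardized with the t-trained scaler).
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_temporal_generalization(Rcpp::NumericVector data_flat,
                                                Rcpp::IntegerVector dims,
                                                Rcpp::IntegerVector folds,
                                                Rcpp::IntegerVector labels,
                                                double lambda) {
  const uword n_trial = dims[0], n_chan = dims[1], n_time = dims[2];
  cube D(data_flat.begin(), n_trial, n_chan, n_time, false);
  uvec y = conv_to<uvec>::from(Rcpp::as<std::vector<int>>(labels));
  ivec fid = conv_to<ivec>::from(Rcpp::as<std::vector<int>>(folds));
  int k = fid.max();
  vec yd = conv_to<vec>::from(y);

  mat tgm(n_time, n_time);
  mat oof(n_trial, n_time);  // reused per training time
  for (uword t = 0; t < n_time; ++t) {
    for (int f = 1; f <= k; ++f) {
      uvec te = find(fid == f);
      uvec tr = find(fid != f);
      vec mu, sd;
      mat Xt = D.slice(t);
      train_scaler(Xt, tr, mu, sd);
      mat Xtr = Xt.rows(tr);
      Xtr.each_row() -= mu.t();
      Xtr.each_row() /= sd.t();
      vec beta = fit_ridge_logistic(Xtr, yd(tr), lambda);
      // apply the t-trained model (and its scaler) to every testing time,
      // with the same arithmetic as the canonical decoder so the diagonal
      // reproduces it bit for bit
      for (uword t2 = 0; t2 < n_time; ++t2) {
        mat Xte = D.slice(t2).rows(te);
        Xte.each_row() -= mu.t();
        Xte.each_row() /= sd.t();
        vec eta = beta(0) + Xte * beta.subvec(1, n_chan);
        vec p = 1.0 / (1.0 + exp(-eta));
        for (uword i = 0; i < te.n_elem; ++i) oof(te(i), t2) = p(i);
      }
    }
    for (uword t2 = 0; t2 < n_time; ++t2) tgm(t, t2) = auc_rank(oof.col(t2), y);
  }
  return Rcpp::wrap(tgm);
}
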