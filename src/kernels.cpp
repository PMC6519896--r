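// Hot loops of the simulator: Monte Carlo win-probability tables and the
// forward ABM run. All randomness goes through R's RNG so results are
// reproducible under set.seed() from the calling R session.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Draw an n x nf predictor matrix and expand to the full design matrix whose
// columns are the term products encoded by bit masks over factors.
// law: 0 = normal(mu, sd), 1 = uniform with the same mean and variance.
void draw_design(int n, int nf, const arma::vec &mu, const arma::vec &sdx,
                 const arma::uvec &masks, int law, arma::mat &X) {
  const double h = std::sqrt(3.0);
  arma::mat x(n, nf);
  for (int j = 0; j < nf; ++j)
    for (int i = 0; i < n; ++i)
      x(i, j) = law == 1 ? R::runif(mu[j] - h * sdx[j], mu[j] + h * sdx[j])
                         : R::rnorm(mu[j], sdx[j]);
  for (arma::uword c = 0; c < masks.n_elem; ++c) {
    arma::vec col(n, arma::fill::ones);
    for (int j = 0; j < nf; ++j)
      if (masks[c] & (1u << j)) col %= x.col(j);
    X.col(c) = col;
  }
}

double rss_of(const arma::mat &X, const arma::vec &y,
              const arma::uvec &cols) {
  arma::mat Xm = X.cols(cols);
  arma::vec b = arma::solve(Xm.t() * Xm, Xm.t() * y,
                            arma::solve_opts::likely_sympd);
  arma::vec r = y - Xm * b;
  return arma::dot(r, r);
}

// Penalized-likelihood score; pen is the full penalty term (2k or k log n).
// Fits whose residual sum is at rounding-noise level relative to the
// response scale (yss = sum y^2) are perfect: they score as the penalty
// minus an offset that dominates every attainable non-perfect score
// (bounded below by ~ -50 n) yet keeps the penalty arithmetic exact, so
// contests between perfect fits are decided by parameter count.
inline double ic_from_rss(double rss, double yss, int n, double pen) {
  if (rss <= 1e-20 * yss) return pen - 1e4 * n;
  return pen + n * (std::log(2.0 * M_PI * rss / n) + 1.0);
}

int sample_row(const NumericMatrix &Q, int row) {
  double u = unif_rand(), acc = 0.0;
  int last = Q.ncol() - 1;
  for (int j = 0; j < Q.ncol(); ++j) {
    acc += Q(row, j);
    if (u <= acc) return j;
  }
  return last;  // guard against rounding in the row sum
}

}  // namespace

// Counts, over `reps` fresh datasets, how often each proposed model's score
// beats each global model's score, for AIC and SC simultaneously.
// model_cols / truth_cols are 1-based column indices into the full design.
// [[Rcpp::export]]
List cpp_win_table(int n, int reps, List model_cols, IntegerVector truth_cols,
                   NumericVector theta, double sigma, NumericVector mu,
                   NumericVector sdx, int nf, NumericVector masks, int law) {
  int nm = model_cols.size();
  std::vector<arma::uvec> cols(nm);
  for (int m = 0; m < nm; ++m) {
    IntegerVector ci = model_cols[m];
    arma::uvec u(ci.size());
    for (int j = 0; j < ci.size(); ++j) u[j] = ci[j] - 1;
    cols[m] = u;
  }
  arma::uvec tcols(truth_cols.size());
  for (int j = 0; j < truth_cols.size(); ++j) tcols[j] = truth_cols[j] - 1;
  arma::vec th(theta.begin(), theta.size());
  arma::vec muv(mu.begin(), mu.size()), sdv(sdx.begin(), sdx.size());
  arma::uvec mk(masks.size());
  for (int j = 0; j < masks.size(); ++j) mk[j] = (arma::uword)masks[j];

  arma::mat X(n, mk.n_elem);
  arma::mat aic_wins(nm, nm, arma::fill::zeros);
  arma::mat sc_wins(nm, nm, arma::fill::zeros);
  arma::vec s_aic(nm), s_sc(nm);
  double logn = std::log((double)n);

  for (int r = 0; r < reps; ++r) {
    draw_design(n, nf, muv, sdv, mk, law, X);
    arma::vec y = X.cols(tcols) * th;
    for (int i = 0; i < n; ++i) y[i] += R::rnorm(0.0, sigma);
    double yss = arma::dot(y, y);
    for (int m = 0; m < nm; ++m) {
      double rss = rss_of(X, y, cols[m]);
      int k = cols[m].n_elem + 1;
      s_aic[m] = ic_from_rss(rss, yss, n, 2.0 * k);
      s_sc[m] = ic_from_rss(rss, yss, n, k * logn);
    }
    for (int p = 0; p < nm; ++p)
      for (int g = 0; g < nm; ++g) {
        if (s_aic[p] < s_aic[g]) aic_wins(p, g) += 1.0;
        if (s_sc[p] < s_sc[g]) sc_wins(p, g) += 1.0;
      }
  }
  return List::create(_["aic"] = wrap(aic_wins), _["sc"] = wrap(sc_wins));
}

// One full ABM trajectory. Scientist types: 0 Tess, 1 Mave, 2 Bo, 3 Rey.
// Q matrices are row-stochastic proposal distributions (row = current
// global). Rey re-runs her predecessor's (proposed, global) contest on fresh
// data; the winner of her own contest becomes the global model. At t = 0 a
// drawn Rey is replaced by a redraw among the proposer types.
// stat: 0 = AIC, 1 = SC. init/truth are 1-based state indices.
// If stop_at_truth, the run ends once the global model first equals the
// truth (used for first-passage-only analyses).
// [[Rcpp::export]]
List cpp_abm_run(int n, int iterations, List model_cols,
                 IntegerVector truth_cols, NumericVector theta, double sigma,
                 NumericVector mu, NumericVector sdx, int nf,
                 NumericVector masks, int law, NumericMatrix Qtess,
                 NumericMatrix Qmave, NumericMatrix Qbo, NumericVector popw,
                 int stat, int init, int truth, bool stop_at_truth) {
  int nm = model_cols.size();
  std::vector<arma::uvec> cols(nm);
  std::vector<int> kpar(nm);
  for (int m = 0; m < nm; ++m) {
    IntegerVector ci = model_cols[m];
    arma::uvec u(ci.size());
    for (int j = 0; j < ci.size(); ++j) u[j] = ci[j] - 1;
    cols[m] = u;
    kpar[m] = ci.size() + 1;
  }
  arma::uvec tcols(truth_cols.size());
  for (int j = 0; j < truth_cols.size(); ++j) tcols[j] = truth_cols[j] - 1;
  arma::vec th(theta.begin(), theta.size());
  arma::vec muv(mu.begin(), mu.size()), sdv(sdx.begin(), sdx.size());
  arma::uvec mk(masks.size());
  for (int j = 0; j < masks.size(); ++j) mk[j] = (arma::uword)masks[j];
  arma::mat X(n, mk.n_elem);
  double logn = std::log((double)n);

  IntegerVector scientist(iterations), proposed(iterations),
      global_before(iterations), global_after(iterations),
      won(iterations), is_rep(iterations), reproduced(iterations);
  NumericVector score_p(iterations), score_g(iterations);

  double cw[4];
  cw[0] = popw[0];
  for (int j = 1; j < 4; ++j) cw[j] = cw[j - 1] + popw[j];
  double nonrey = popw[0] + popw[1] + popw[2];

  int g = init - 1;
  int prev_p = -1, prev_g = -1, prev_won = 0;
  int steps = 0;

  auto score_pair = [&](int a, int b, double &sa, double &sb) {
    arma::vec y = X.cols(tcols) * th;
    for (int i = 0; i < n; ++i) y[i] += R::rnorm(0.0, sigma);
    double yss = arma::dot(y, y);
    double rss_a = rss_of(X, y, cols[a]);
    sa = ic_from_rss(rss_a, yss, n,
                     stat == 0 ? 2.0 * kpar[a] : kpar[a] * logn);
    if (b == a) { sb = sa; return; }
    double rss_b = rss_of(X, y, cols[b]);
    sb = ic_from_rss(rss_b, yss, n,
                     stat == 0 ? 2.0 * kpar[b] : kpar[b] * logn);
  };

  for (int t = 0; t < iterations; ++t) {
    double u = unif_rand() * cw[3];
    int type = u <= cw[0] ? 0 : (u <= cw[1] ? 1 : (u <= cw[2] ? 2 : 3));
    if (type == 3 && prev_p < 0) {
      // no predecessor to replicate: redraw among proposer types
      if (nonrey > 0) {
        double v = unif_rand() * nonrey;
        type = v <= popw[0] ? 0 : (v <= popw[0] + popw[1] ? 1 : 2);
      } else {
        type = (int)std::floor(unif_rand() * 3.0);
        if (type > 2) type = 2;
      }
    }

    int p_idx, gb_idx, w, rep_ok = NA_INTEGER, isrep = 0;
    double sp, sg;
    draw_design(n, nf, muv, sdv, mk, law, X);
    if (type == 3) {
      isrep = 1;
      p_idx = prev_p;
      gb_idx = prev_g;
      score_pair(p_idx, gb_idx, sp, sg);
      w = (p_idx != gb_idx && sp < sg) ? 1 : 0;
      rep_ok = (w == prev_won) ? 1 : 0;
      g = w ? p_idx : gb_idx;
    } else {
      const NumericMatrix &Q = type == 0 ? Qtess : (type == 1 ? Qmave : Qbo);
      p_idx = sample_row(Q, g);
      gb_idx = g;
      score_pair(p_idx, gb_idx, sp, sg);
      w = (p_idx != gb_idx && sp < sg) ? 1 : 0;
      g = w ? p_idx : gb_idx;
    }

    scientist[t] = type + 1;
    proposed[t] = p_idx + 1;
    global_before[t] = gb_idx + 1;
    global_after[t] = g + 1;
    won[t] = w;
    is_rep[t] = isrep;
    reproduced[t] = isrep ? rep_ok : NA_INTEGER;
    score_p[t] = sp;
    score_g[t] = sg;
    prev_p = p_idx;
    prev_g = gb_idx;
    prev_won = w;
    steps = t + 1;
    if (stop_at_truth && g == truth - 1) break;
  }

  IntegerVector idx = seq_len(steps) - 1;
  return List::create(
      _["scientist"] = scientist[idx], _["proposed"] = proposed[idx],
      _["global_before"] = global_before[idx],
      _["global_after"] = global_after[idx], _["won"] = won[idx],
      _["is_replication"] = is_rep[idx], _["reproduced"] = reproduced[idx],
      _["score_proposed"] = score_p[idx], _["score_global"] = score_g[idx]);
}
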