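// Gibbs sampler for Gaussian linear mixed models with random-intercept and
// correlated random-slope blocks, plus a weighted-observation likelihood so
// that identical rows can be collapsed to sufficient statistics
// (weight w_i, cell mean y_i, and a pooled within-cell sum of squares).
//
// Model: y_i ~ N(x_i' beta + sum_j z_{ji}' u_{j, g_j(i)}, sigma^2 / w_i)
//   beta       ~ N(0, beta_prior_var * I)
//   u_{jl}     ~ N(0, G_j),  G_j ~ IW(nu_j * V_j, nu_j)
//                 (prior expectation nu_j V_j / (nu_j - d - 1) when defined)
//   sigma^2    ~ IG(nu_r / 2, nu_r V_r / 2)
// The total residual sum of squares also accrues ss_extra, the pooled
// within-cell variation lost by collapsing, and the residual degrees of
// freedom use sum(w) rather than the number of collapsed rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat rinvwishart(const arma::mat &scale, double df, int &jitter_count) {
  // Draw G ~ IW(scale, df) via G^{-1} ~ Wishart(df, scale^{-1}) (Bartlett).
  const int d = scale.n_rows;
  arma::mat S = scale;
  arma::mat Sinv;
  // guard against numerically non-PD scale matrices: add jitter and log
  for (int attempt = 0; attempt < 50; ++attempt) {
    bool ok = arma::inv_sympd(Sinv, S);
    if (ok) break;
    S.diag() += 1e-8 * (1.0 + arma::trace(S) / d);
    ++jitter_count;
  }
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat W = L * A * A.t() * L.t();  // Wishart(df, Sinv)
  arma::mat G;
  if (!arma::inv_sympd(G, W)) {
    W.diag() += 1e-8 * (1.0 + arma::trace(W) / d);
    ++jitter_count;
    G = arma::inv_sympd(W);
  }
  return G;
}

// [[Rcpp::export]]
List gibbs_lmm_cpp(const arma::vec &y,
                   const arma::vec &w,
                   double ss_extra,
                   const arma::mat &X,
                   const List &group_idx,   // per block: 0-based level per row
                   const List &Zmats,       // per block: n x d within-group design
                   const IntegerVector &nlev,
                   const List &priorV,      // per block: d x d scale
                   const NumericVector &priorNu,
                   double resid_V, double resid_nu,
                   double beta_prior_var,
                   int n_iter, int burn_in, int thin,
                   bool keep_ranef) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int nblocks = group_idx.size();
  const double n_total = arma::accu(w);

  // Precompute weighted fixed-effect cross products
  arma::mat Xw = X.each_col() % w;
  arma::mat XtWX = X.t() * Xw;

  // Block bookkeeping
  std::vector<arma::uvec> gidx(nblocks);
  std::vector<arma::mat> Z(nblocks);
  std::vector<int> dim(nblocks), q(nblocks);
  std::vector<std::vector<arma::uvec>> rows_of(nblocks);  // rows per level
  std::vector<std::vector<arma::mat>> Cw(nblocks);        // sum w z z' per level
  std::vector<arma::mat> G(nblocks), Ginv(nblocks), Vp(nblocks);
  std::vector<arma::mat> U(nblocks);                      // q x d effects
  std::vector<arma::vec> fit(nblocks);

  for (int b = 0; b < nblocks; ++b) {
    IntegerVector gi = group_idx[b];
    gidx[b] = arma::conv_to<arma::uvec>::from(
        arma::Col<int>(gi.begin(), gi.size()));
    Z[b] = as<arma::mat>(Zmats[b]);
    dim[b] = Z[b].n_cols;
    q[b] = nlev[b];
    Vp[b] = as<arma::mat>(priorV[b]);
    G[b] = Vp[b];  // start at prior scale
    Ginv[b] = arma::inv_sympd(G[b]);
    U[b].zeros(q[b], dim[b]);
    fit[b].zeros(n);
    rows_of[b].resize(q[b]);
    Cw[b].resize(q[b]);
    std::vector<std::vector<arma::uword>> tmp(q[b]);
    for (int i = 0; i < n; ++i) tmp[gidx[b](i)].push_back(i);
    for (int l = 0; l < q[b]; ++l) {
      rows_of[b][l] = arma::uvec(tmp[l]);
      arma::mat Zl = Z[b].rows(rows_of[b][l]);
      arma::vec wl = w.elem(rows_of[b][l]);
      Cw[b][l] = Zl.t() * (Zl.each_col() % wl);
    }
  }

  arma::vec beta(p, arma::fill::zeros);
  double sigma2 = 1.0;
  {
    // crude initial residual variance from the weighted data
    double ybar = arma::dot(w, y) / n_total;
    double ss = arma::dot(w, arma::square(y - ybar)) + ss_extra;
    sigma2 = std::max(ss / std::max(n_total - 1.0, 1.0), 1e-8);
  }

  int n_keep = (n_iter - burn_in) / thin;
  int n_gpar = 0;
  for (int b = 0; b < nblocks; ++b) n_gpar += dim[b] * (dim[b] + 1) / 2;
  int n_upar = 0;
  if (keep_ranef) for (int b = 0; b < nblocks; ++b) n_upar += q[b] * dim[b];
  arma::mat draws(n_keep, p + n_upar + n_gpar + 1);
  int jitter_count = 0;

  arma::vec total_fit(n, arma::fill::zeros);
  int keep_row = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- fixed effects ----
    arma::vec r_nf = y - total_fit;
    arma::mat A = XtWX / sigma2;
    A.diag() += 1.0 / beta_prior_var;
    arma::vec bvec = (Xw.t() * r_nf) / sigma2;
    arma::mat Rch = arma::chol(A);  // upper: A = R'R
    arma::vec mu = arma::solve(arma::trimatu(Rch),
                               arma::solve(arma::trimatl(Rch.t()), bvec));
    arma::vec z(p);
    for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(Rch), z);
    arma::vec xb = X * beta;
    arma::vec r_base = y - xb;

    // ---- random-effect blocks ----
    for (int b = 0; b < nblocks; ++b) {
      arma::vec r_j = r_base - (total_fit - fit[b]);
      const int d = dim[b];
      for (int l = 0; l < q[b]; ++l) {
        const arma::uvec &rows = rows_of[b][l];
        arma::vec m(d, arma::fill::zeros);
        for (arma::uword k = 0; k < rows.n_elem; ++k) {
          const arma::uword i = rows(k);
          for (int c = 0; c < d; ++c) m(c) += w(i) * Z[b](i, c) * r_j(i);
        }
        arma::mat P = Cw[b][l] / sigma2 + Ginv[b];
        arma::mat Rl = arma::chol(P);
        arma::vec mul = arma::solve(arma::trimatu(Rl),
                                    arma::solve(arma::trimatl(Rl.t()), m / sigma2));
        arma::vec zl(d);
        for (int c = 0; c < d; ++c) zl(c) = R::norm_rand();
        arma::vec ul = mul + arma::solve(arma::trimatu(Rl), zl);
        U[b].row(l) = ul.t();
      }
      // refresh this block's contribution
      arma::vec newfit(n);
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) s += Z[b](i, c) * U[b](gidx[b](i), c);
        newfit(i) = s;
      }
      total_fit += newfit - fit[b];
      fit[b] = newfit;

      // ---- block covariance ----
      arma::mat S = U[b].t() * U[b];
      arma::mat scale = priorNu[b] * Vp[b] + S;
      double df = priorNu[b] + q[b];
      if (d == 1) {
        G[b](0, 0) = scale(0, 0) / R::rchisq(df);
        Ginv[b](0, 0) = 1.0 / G[b](0, 0);
      } else {
        G[b] = rinvwishart(scale, df, jitter_count);
        if (!arma::inv_sympd(Ginv[b], G[b])) {
          G[b].diag() += 1e-8 * (1.0 + arma::trace(G[b]) / d);
          ++jitter_count;
          Ginv[b] = arma::inv_sympd(G[b]);
        }
      }
    }

    // ---- residual variance ----
    arma::vec r_all = r_base - total_fit;
    double rss = arma::dot(w, arma::square(r_all)) + ss_extra;
    sigma2 = (resid_nu * resid_V + rss) / R::rchisq(resid_nu + n_total);

    // ---- store ----
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep_row < n_keep) {
      int col = 0;
      for (int k = 0; k < p; ++k) draws(keep_row, col++) = beta(k);
      if (keep_ranef) {
        for (int b = 0; b < nblocks; ++b)
          for (int l = 0; l < q[b]; ++l)
            for (int c = 0; c < dim[b]; ++c)
              draws(keep_row, col++) = U[b](l, c);
      }
      for (int b = 0; b < nblocks; ++b) {
        const int d = dim[b];
        for (int c1 = 0; c1 < d; ++c1)
          for (int c2 = c1; c2 < d; ++c2)
            draws(keep_row, col++) = G[b](c1, c2);
      }
      draws(keep_row, col++) = sigma2;
      ++keep_row;
    }
  }

  return List::create(_["draws"] = draws,
                      _["n_kept"] = keep_row,
                      _["jitter_count"] = jitter_count);
}

// Weighted pool-adjacent-violators: least-squares non-decreasing fit.
// [[Rcpp::export]]
NumericVector pava_cpp(const NumericVector &y, const NumericVector &w) {
  const int n = y.size();
  NumericVector fit(n);
  if (n == 0) return fit;
  std::vector<double> level(n), weight(n);
  std::vector<int> count(n);
  int top = -1;
  for (int i = 0; i < n; ++i) {
    ++top;
    level[top] = y[i];
    weight[top] = w[i];
    count[top] = 1;
    while (top > 0 && level[top - 1] > level[top]) {
      double wsum = weight[top - 1] + weight[top];
      level[top - 1] = (weight[top - 1] * level[top - 1] +
                        weight[top] * level[top]) / wsum;
      weight[top - 1] = wsum;
      count[top - 1] += count[top];
      --top;
    }
  }
  int i = 0;
  for (int b = 0; b <= top; ++b)
    for (int k = 0; k < count[b]; ++k) fit[i++] = level[b];
  return fit;
}
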