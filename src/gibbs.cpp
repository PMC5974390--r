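// Gibbs sampler for Bayesian matrix factorization with side information on
// both axes (drugs x cell lines).  All randomness goes through R's RNG so a
// prior set.seed() makes the chain bit-reproducible.
//
// Model (per observed entry, response already centred by its observed mean):
//   y_ij ~ N(d_i' c_j, 1/alpha)
//   d_i  ~ N(mu_D + betaD' x_i, LambdaD^-1)      (x_i absent -> N(mu_D, .))
//   c_j  ~ N(mu_C + betaC' z_j, LambdaC^-1)
//   (mu, Lambda) ~ Normal-Wishart(mu0 = 0, b0, W0 = I, nu0 = L) per axis
//   beta | Lambda, lambda_beta ~ MatrixNormal(0, lambda_beta^-1 I_F, Lambda^-1)
//   lambda_beta ~ Gamma(shape, rate);  alpha ~ Gamma(shape, rate) if adaptive.

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

static arma::mat rnorm_mat(int r, int c) {
  arma::mat z(r, c);
  // column-major fill: same order R would fill a matrix
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) z(i, j) = norm_rand();
  return z;
}

// Wishart(nu, W) via Bartlett; W must be symmetric positive-definite.
static arma::mat rwishart(double nu, const arma::mat& W, int iter_for_error) {
  arma::mat Rw;
  if (!arma::chol(Rw, W)) // upper: W = Rw' Rw
    stop("Wishart scale matrix not positive-definite at iteration %d",
         iter_for_error);
  const int p = W.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(Rf_rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = Rw.t() * A;      // lower-tri factor of the draw
  return LA * LA.t();
}

// Draw from N(P^-1 h, P^-1) given precision P (upper-chol factor computed here).
static arma::vec rmvnorm_prec(const arma::mat& P, const arma::vec& h,
                              int iter_for_error) {
  arma::mat Ru;
  if (!arma::chol(Ru, P))
    stop("latent precision matrix not positive-definite at iteration %d",
         iter_for_error);
  arma::vec mean = arma::solve(arma::trimatu(Ru),
                               arma::solve(arma::trimatl(Ru.t()), h));
  return mean + arma::solve(arma::trimatu(Ru), rnorm_vec(P.n_rows));
}

struct AxisState {
  arma::mat U;        // L x N latents
  arma::mat beta;     // F x L link matrix (F = 0 when no side info)
  arma::vec mu;       // L
  arma::mat Lambda;   // L x L precision
  double lambda_beta; // link precision scale
  bool has_side;
  arma::mat X;        // F x N side info (scaled)
};

// One sweep of hyperparameter + link-matrix + latent updates for one axis.
// Vother: L x M latents of the other axis; obs_idx[i]: indices of observed
// partners of entity i; obs_val[i]: matching centred responses.
static void update_axis(AxisState& st, const arma::mat& Vother,
                        const std::vector<arma::uvec>& obs_idx,
                        const std::vector<arma::vec>& obs_val,
                        double alpha, double b0, double beta_shape,
                        double beta_rate, int iter) {
  const int L = st.U.n_rows;
  const int N = st.U.n_cols;

  // ---- (mu, Lambda) Normal-Wishart update on residuals r_i = u_i - beta'x_i
  arma::mat Rres = st.U;
  if (st.has_side) Rres -= st.beta.t() * st.X;
  arma::vec rbar = arma::mean(Rres, 1);
  arma::mat S = Rres * Rres.t() - double(N) * (rbar * rbar.t());
  double bN = b0 + N;
  arma::vec muN = (double(N) * rbar) / bN;            // mu0 = 0
  double nuN = L + N;                                  // nu0 = L
  arma::mat Winv = arma::eye(L, L) + S +
    (b0 * double(N) / bN) * (rbar * rbar.t());         // W0 = I
  if (st.has_side) {
    nuN += st.beta.n_rows;
    Winv += st.lambda_beta * (st.beta.t() * st.beta);
  }
  arma::mat WN = arma::inv_sympd(arma::symmatu(Winv));
  st.Lambda = rwishart(nuN, arma::symmatu(WN), iter);
  {
    arma::mat Ru;
    if (!arma::chol(Ru, bN * st.Lambda))
      stop("hyperprior precision not positive-definite at iteration %d", iter);
    st.mu = muN + arma::solve(arma::trimatu(Ru), rnorm_vec(L));
  }

  if (st.has_side) {
    const int F = st.X.n_rows;
    // ---- lambda_beta | beta, Lambda
    double shape = beta_shape + 0.5 * double(F) * double(L);
    double rate = beta_rate +
      0.5 * arma::trace(st.Lambda * (st.beta.t() * st.beta));
    st.lambda_beta = Rf_rgamma(shape, 1.0 / rate);

    // ---- beta | U, mu, Lambda, lambda_beta: matrix normal
    arma::mat Util = st.U.each_col() - st.mu;          // L x N
    arma::mat K = st.X * st.X.t() +
      st.lambda_beta * arma::eye(F, F);                // F x F row precision
    arma::mat Rk;
    if (!arma::chol(Rk, arma::symmatu(K)))
      stop("link-matrix precision not positive-definite at iteration %d", iter);
    arma::mat M = arma::solve(arma::trimatu(Rk),
                   arma::solve(arma::trimatl(Rk.t()), st.X * Util.t()));
    arma::mat RL;
    if (!arma::chol(RL, arma::symmatu(st.Lambda)))
      stop("axis precision not positive-definite at iteration %d", iter);
    arma::mat Z = arma::solve(arma::trimatu(Rk), rnorm_mat(F, L));
    // column factor: Z * RL^-T  ==  solve(RL, Z')'
    st.beta = M + arma::solve(arma::trimatu(RL), Z.t()).t();
  }

  // ---- latents
  arma::vec prior_h0 = st.Lambda * st.mu;
  arma::mat side_mean;                                 // L x N
  if (st.has_side) side_mean = st.beta.t() * st.X;
  for (int i = 0; i < N; ++i) {
    const arma::uvec& idx = obs_idx[i];
    arma::mat Vsub = Vother.cols(idx);                 // L x n_i
    arma::mat P = st.Lambda + alpha * (Vsub * Vsub.t());
    arma::vec h = st.has_side
      ? arma::vec(st.Lambda * (st.mu + side_mean.col(i)))
      : prior_h0;
    h += alpha * (Vsub * obs_val[i]);
    st.U.col(i) = rmvnorm_prec(arma::symmatu(P), h, iter);
  }
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::mat& Y,          // n_drugs x n_cells, NaN = missing
                const arma::mat& Xd,         // F_D x n_drugs (0 x n when absent)
                const arma::mat& Xc,         // F_C x n_cells
                int L, int burn_in, int n_collect,
                bool adaptive_alpha, double alpha_init,
                double alpha_shape, double alpha_rate,
                double beta_shape, double beta_rate,
                double b0) {
  const int Nd = Y.n_rows, Nc = Y.n_cols;
  const bool has_d = Xd.n_rows > 0, has_c = Xc.n_rows > 0;
  const int Fd = Xd.n_rows, Fc = Xc.n_rows;

  // observation lists per row and per column
  std::vector<arma::uvec> row_idx(Nd), col_idx(Nc);
  std::vector<arma::vec> row_val(Nd), col_val(Nc);
  {
    std::vector<std::vector<arma::uword>> ri(Nd), ci(Nc);
    std::vector<std::vector<double>> rv(Nd), cv(Nc);
    for (int j = 0; j < Nc; ++j)
      for (int i = 0; i < Nd; ++i)
        if (arma::is_finite(Y(i, j))) {
          ri[i].push_back(j); rv[i].push_back(Y(i, j));
          ci[j].push_back(i); cv[j].push_back(Y(i, j));
        }
    for (int i = 0; i < Nd; ++i) {
      row_idx[i] = arma::uvec(ri[i]); row_val[i] = arma::vec(rv[i]);
    }
    for (int j = 0; j < Nc; ++j) {
      col_idx[j] = arma::uvec(ci[j]); col_val[j] = arma::vec(cv[j]);
    }
  }
  double n_obs = 0;
  for (int i = 0; i < Nd; ++i) n_obs += row_idx[i].n_elem;

  AxisState D, C;
  D.U = 0.1 * rnorm_mat(L, Nd); D.beta = arma::zeros(Fd, L);
  D.mu = arma::zeros(L); D.Lambda = arma::eye(L, L);
  D.lambda_beta = 1.0; D.has_side = has_d; D.X = Xd;
  C.U = 0.1 * rnorm_mat(L, Nc); C.beta = arma::zeros(Fc, L);
  C.mu = arma::zeros(L); C.Lambda = arma::eye(L, L);
  C.lambda_beta = 1.0; C.has_side = has_c; C.X = Xc;
  double alpha = alpha_init;

  const int S = n_collect;
  arma::cube Ds(L, Nd, S), Cs(L, Nc, S);
  arma::cube betaDs(std::max(Fd, 1), L, has_d ? S : 0);
  arma::cube betaCs(std::max(Fc, 1), L, has_c ? S : 0);
  arma::mat muDs(L, S), muCs(L, S);
  arma::cube LambdaDs(L, L, S), LambdaCs(L, L, S);
  arma::vec alphas(S), lambdaDs(S), lambdaCs(S);

  const int total = burn_in + n_collect;
  for (int it = 0; it < total; ++it) {
    if (adaptive_alpha) {
      double ssr = 0;
      for (int i = 0; i < Nd; ++i) {
        if (row_idx[i].n_elem == 0) continue;
        arma::vec pred = (C.U.cols(row_idx[i])).t() * D.U.col(i);
        ssr += arma::accu(arma::square(row_val[i] - pred));
      }
      alpha = Rf_rgamma(alpha_shape + 0.5 * n_obs,
                        1.0 / (alpha_rate + 0.5 * ssr));
    }
    update_axis(D, C.U, row_idx, row_val, alpha, b0,
                beta_shape, beta_rate, it);
    update_axis(C, D.U, col_idx, col_val, alpha, b0,
                beta_shape, beta_rate, it);

    if (it >= burn_in) {
      int s = it - burn_in;
      Ds.slice(s) = D.U; Cs.slice(s) = C.U;
      if (has_d) betaDs.slice(s) = D.beta;
      if (has_c) betaCs.slice(s) = C.beta;
      muDs.col(s) = D.mu; muCs.col(s) = C.mu;
      LambdaDs.slice(s) = D.Lambda; LambdaCs.slice(s) = C.Lambda;
      alphas[s] = alpha;
      lambdaDs[s] = D.lambda_beta; lambdaCs[s] = C.lambda_beta;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["D"] = Ds, _["C"] = Cs,
    _["beta_D"] = betaDs, _["beta_C"] = betaCs,
    _["mu_D"] = muDs, _["mu_C"] = muCs,
    _["Lambda_D"] = LambdaDs, _["Lambda_C"] = LambdaCs,
    _["alpha"] = alphas,
    _["lambda_beta_D"] = lambdaDs, _["lambda_beta_C"] = lambdaCs);
}
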