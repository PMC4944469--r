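// Gibbs sampler for the phylogenetic linear mixed model
//   y = X beta + Za u_a + Zb u_b + e
//   u_a ~ N(0, s2a * V_lambda)  (species level; V from the phylogeny,
//                                V_lambda = lambda*V + (1-lambda)*I)
//   u_b ~ N(0, s2b * I)         (breed within species; may be absent)
//   e   ~ N(0, s2e * I)
// Flat prior on beta; inverse-gamma(shape, scale) priors on variances;
// uniform(0,1) prior on the phylogenetic-signal parameter lambda.
// (beta, u) is updated jointly from its multivariate-normal conditional,
// each variance from its scaled inverse-chi-squared conditional, and
// lambda by a reflected random-walk Metropolis step. Because V_lambda
// shares the eigenvectors Q of V (V = Q diag(d) Q'), its inverse and
// log-determinant come from the shifted eigenvalues lambda*d + 1 - lambda.
// Uses R's RNG so set.seed() in R makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// log density kernel of u_a | s2a, lambda (w = Q'u_a fixed)
static double lambda_logpost(double lam, const arma::vec& w,
                             const arma::vec& d, double s2a) {
  arma::vec e = lam * d + (1.0 - lam);
  return -0.5 * arma::sum(arma::log(e)) -
    0.5 * arma::sum(arma::square(w) / e) / s2a;
}

// [[Rcpp::export]]
List gibbs_lmm_cpp(const arma::vec& y,
                   const arma::mat& X,
                   const arma::mat& Za,
                   const arma::mat& Zb,
                   const arma::mat& Q,      // eigenvectors of V
                   const arma::vec& d,      // eigenvalues of V
                   int n_iter, int burn_in, int thin,
                   const arma::vec& prior_shape,   // phylo, breed, resid
                   const arma::vec& prior_scale,
                   const arma::vec& fixed_var,     // < 0 means "estimate"
                   bool sample_lambda,
                   double lambda_init,
                   double mh_sd,
                   bool prior_only) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int qa = Za.n_cols;
  const int qb = Zb.n_cols;
  const int P = p + qa + qb;

  arma::mat W(n, P);
  W.cols(0, p - 1) = X;
  if (qa > 0) W.cols(p, p + qa - 1) = Za;
  if (qb > 0) W.cols(p + qa, P - 1) = Zb;
  const arma::mat WtW = W.t() * W;
  const arma::vec Wty = W.t() * y;
  const double yty = arma::dot(y, y);

  double vy = arma::var(y);
  if (vy <= 0) vy = 1e-6;
  double s2a = fixed_var[0] >= 0 ? fixed_var[0] : vy / 4.0;
  double s2b = fixed_var[1] >= 0 ? fixed_var[1] : vy / 4.0;
  double s2e = fixed_var[2] >= 0 ? fixed_var[2] : vy / 2.0;
  double lam = lambda_init;

  arma::vec evals = lam * d + (1.0 - lam);
  arma::mat Vinv = Q * arma::diagmat(1.0 / evals) * Q.t();

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(n_keep, p, arma::fill::zeros);
  arma::mat var_draws(n_keep, 3, arma::fill::zeros);
  arma::vec lambda_draws(n_keep, arma::fill::zeros);
  int n_accept = 0, n_prop = 0;

  arma::vec theta(P, arma::fill::zeros);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (!prior_only) {
      arma::mat C = WtW / s2e;
      if (qa > 0) C.submat(p, p, p + qa - 1, p + qa - 1) += Vinv / s2a;
      if (qb > 0) {
        for (int j = p + qa; j < P; ++j) C(j, j) += 1.0 / s2b;
      }
      arma::mat Rch;
      if (!arma::chol(Rch, C)) {
        C.diag() += 1e-8 * arma::max(C.diag());
        if (!arma::chol(Rch, C)) stop("Cholesky of the conditional precision failed");
      }
      arma::vec m = arma::solve(arma::trimatu(Rch),
                                arma::solve(arma::trimatl(Rch.t()), Wty / s2e));
      arma::vec z(P);
      for (int j = 0; j < P; ++j) z[j] = R::norm_rand();
      theta = m + arma::solve(arma::trimatu(Rch), z);
    }

    if (prior_only) {
      if (fixed_var[0] < 0) s2a = rinvgamma(prior_shape[0], prior_scale[0]);
      if (fixed_var[1] < 0 && qb > 0) s2b = rinvgamma(prior_shape[1], prior_scale[1]);
      if (fixed_var[2] < 0) s2e = rinvgamma(prior_shape[2], prior_scale[2]);
      if (sample_lambda) lam = R::runif(0.0, 1.0);
    } else {
      arma::vec ua, w;
      if (qa > 0) {
        ua = theta.subvec(p, p + qa - 1);
        w = Q.t() * ua;
      }
      if (qa > 0 && fixed_var[0] < 0) {
        double quad = arma::sum(arma::square(w) / evals);
        s2a = rinvgamma(prior_shape[0] + qa / 2.0, prior_scale[0] + quad / 2.0);
      }
      if (qa > 0 && sample_lambda) {
        // reflected random-walk Metropolis on [0, 1]
        double prop = lam + R::norm_rand() * mh_sd;
        while (prop < 0.0 || prop > 1.0) {
          if (prop < 0.0) prop = -prop;
          if (prop > 1.0) prop = 2.0 - prop;
        }
        double logr = lambda_logpost(prop, w, d, s2a) -
          lambda_logpost(lam, w, d, s2a);
        ++n_prop;
        if (R::unif_rand() < std::exp(std::min(0.0, logr))) {
          lam = prop;
          ++n_accept;
          evals = lam * d + (1.0 - lam);
          Vinv = Q * arma::diagmat(1.0 / evals) * Q.t();
        }
      }
      if (qb > 0 && fixed_var[1] < 0) {
        arma::vec ub = theta.subvec(p + qa, P - 1);
        s2b = rinvgamma(prior_shape[1] + qb / 2.0,
                        prior_scale[1] + arma::dot(ub, ub) / 2.0);
      }
      if (fixed_var[2] < 0) {
        double rss = yty - 2.0 * arma::dot(theta, Wty) +
          arma::as_scalar(theta.t() * WtW * theta);
        if (rss < 0) rss = 0;
        s2e = rinvgamma(prior_shape[2] + n / 2.0, prior_scale[2] + rss / 2.0);
      }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_draws.row(kept) = theta.subvec(0, p - 1).t();
      var_draws(kept, 0) = s2a;
      var_draws(kept, 1) = qb > 0 ? s2b : 0.0;
      var_draws(kept, 2) = s2e;
      lambda_draws[kept] = lam;
      ++kept;
    }
  }

  return List::create(Named("beta") = beta_draws,
                      Named("variances") = var_draws,
                      Named("lambda") = lambda_draws,
                      Named("accept_rate") =
                        n_prop > 0 ? double(n_accept) / n_prop : NA_REAL,
                      Named("n_kept") = kept);
}
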