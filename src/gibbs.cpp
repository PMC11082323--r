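// Single-site (GIBBS1F90-style) Gibbs sampler for the bivariate animal model
//
//   y = X beta + Z a + e,   a ~ N(0, G0 (x) H),   e_t ~ N(0, I sigma2_e[t])
//
// with an inverted-Wishart prior on the 2x2 genetic (co)variance matrix and
// scaled inverse chi-square priors on the per-trait residual variances.
// Uses R's RNG throughout so a single set.seed() in R governs determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// G0 ~ IW(S, df): draw W ~ Wishart(S^-1, df) by Bartlett, return W^-1.
static arma::mat rinvwishart(double df, const arma::mat& S) {
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  const int d = S.n_rows;
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export(name = ".gibbs_bivariate_cpp")]]
List gibbs_bivariate_cpp(const arma::vec& y,
                         const arma::mat& X,
                         const arma::ivec& animal,   // 0-based
                         const arma::ivec& trait,    // 0 / 1
                         const arma::mat& Hinv,
                         int n_iter, int burn_in, int thin,
                         double nu_g, const arma::mat& S_g,
                         double nu_e, const arma::vec& s_e,
                         bool update_vc,
                         const arma::mat& G0_init,
                         const arma::vec& se_init,
                         bool block_animal) {
  const int n_rec = y.n_elem;
  const int p = X.n_cols;
  const int n = Hinv.n_rows;

  // records per animal (each record carries the animal's own trait)
  std::vector<std::vector<int>> recs(n);
  for (int r = 0; r < n_rec; ++r) recs[animal[r]].push_back(r);
  arma::ivec nrec_t(2, arma::fill::zeros);
  for (int r = 0; r < n_rec; ++r) nrec_t[trait[r]] += 1;

  arma::vec beta(p, arma::fill::zeros);
  arma::mat a(n, 2, arma::fill::zeros);
  arma::mat G0 = G0_init;
  arma::vec se = se_init;
  arma::vec e = y;   // residuals (all effects start at 0)

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  arma::mat vc_chain(n_keep, 5, arma::fill::zeros);
  arma::mat beta_chain(n_keep, p, arma::fill::zeros);
  arma::mat a_sum(n, 2, arma::fill::zeros);
  arma::mat a_sq(n, 2, arma::fill::zeros);
  int kept = 0;
  int pd_failures = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    arma::mat G0inv;
    bool ok = arma::inv_sympd(G0inv, arma::symmatu(G0));
    if (!ok) {
      G0.diag() += 1e-8 * arma::trace(G0);
      ++pd_failures;
      if (!arma::inv_sympd(G0inv, arma::symmatu(G0)))
        stop("genetic covariance matrix persistently non-positive-definite");
    }

    // --- fixed effects (flat prior) ---
    for (int j = 0; j < p; ++j) {
      double num = 0.0, den = 0.0;
      for (int r = 0; r < n_rec; ++r) {
        double w = X(r, j);
        if (w == 0.0) continue;
        double ri = 1.0 / se[trait[r]];
        num += w * (e[r] + w * beta[j]) * ri;
        den += w * w * ri;
      }
      if (den <= 0.0) continue;
      double newb = num / den + R::rnorm(0.0, 1.0) / std::sqrt(den);
      double delta = newb - beta[j];
      if (delta != 0.0) {
        beta[j] = newb;
        for (int r = 0; r < n_rec; ++r) {
          double w = X(r, j);
          if (w != 0.0) e[r] -= w * delta;
        }
      }
    }

    // --- breeding values ---
    if (block_animal) {
      // joint 2x2 update of both trait effects per animal
      for (int i = 0; i < n; ++i) {
        double hd0 = arma::dot(Hinv.col(i), a.col(0)) - Hinv(i, i) * a(i, 0);
        double hd1 = arma::dot(Hinv.col(i), a.col(1)) - Hinv(i, i) * a(i, 1);
        arma::vec rhs(2);
        rhs[0] = -(G0inv(0, 0) * hd0 + G0inv(0, 1) * hd1);
        rhs[1] = -(G0inv(1, 0) * hd0 + G0inv(1, 1) * hd1);
        arma::mat P = Hinv(i, i) * G0inv;
        for (int r : recs[i]) {
          int t = trait[r];
          double ri = 1.0 / se[t];
          rhs[t] += (e[r] + a(i, t)) * ri;
          P(t, t) += ri;
        }
        arma::mat L = arma::chol(P, "lower");
        arma::vec mu = arma::solve(arma::trimatu(L.t()),
                                   arma::solve(arma::trimatl(L), rhs));
        arma::vec zdraw(2);
        zdraw[0] = R::rnorm(0.0, 1.0);
        zdraw[1] = R::rnorm(0.0, 1.0);
        arma::vec newa = mu + arma::solve(arma::trimatu(L.t()), zdraw);
        double d0 = newa[0] - a(i, 0);
        double d1 = newa[1] - a(i, 1);
        a(i, 0) = newa[0];
        a(i, 1) = newa[1];
        for (int r : recs[i]) e[r] -= (trait[r] == 0) ? d0 : d1;
      }
    } else {
    // single-site scan over (animal, trait)
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < 2; ++t) {
        int o = 1 - t;
        // Hinv is symmetric; column views are contiguous in memory
        double hdot_t = arma::dot(Hinv.col(i), a.col(t));
        double hdot_o = arma::dot(Hinv.col(i), a.col(o));
        double cterm = G0inv(t, t) * (hdot_t - Hinv(i, i) * a(i, t)) +
                       G0inv(t, o) * hdot_o;
        double prec = G0inv(t, t) * Hinv(i, i);
        double num = -cterm;
        for (int r : recs[i]) {
          if (trait[r] != t) continue;
          double ri = 1.0 / se[t];
          num += (e[r] + a(i, t)) * ri;
          prec += ri;
        }
        double newa = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        double delta = newa - a(i, t);
        a(i, t) = newa;
        for (int r : recs[i]) {
          if (trait[r] == t) e[r] -= delta;
        }
      }
    }
    }

    // --- (co)variance components ---
    if (update_vc) {
      arma::mat Sa = a.t() * Hinv * a;           // 2x2 quadratic form
      G0 = rinvwishart(nu_g + n, S_g + Sa);
      for (int t = 0; t < 2; ++t) {
        double sse = 0.0;
        for (int r = 0; r < n_rec; ++r) {
          if (trait[r] == t) sse += e[r] * e[r];
        }
        se[t] = (sse + nu_e * s_e[t]) / R::rchisq(nrec_t[t] + nu_e);
      }
    }

    // periodic residual refresh against numeric drift
    if (iter % 1000 == 0) {
      e = y - X * beta;
      for (int r = 0; r < n_rec; ++r) e[r] -= a(animal[r], trait[r]);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      vc_chain(kept, 0) = G0(0, 0);
      vc_chain(kept, 1) = G0(0, 1);
      vc_chain(kept, 2) = G0(1, 1);
      vc_chain(kept, 3) = se[0];
      vc_chain(kept, 4) = se[1];
      beta_chain.row(kept) = beta.t();
      a_sum += a;
      a_sq += a % a;
      ++kept;
    }
  }

  arma::mat a_mean = a_sum / std::max(kept, 1);
  arma::mat a_sd(n, 2, arma::fill::zeros);
  if (kept > 1) {
    a_sd = arma::sqrt(arma::clamp(
      (a_sq - a_sum % a_sum / kept) / (kept - 1), 0.0, arma::datum::inf));
  }
  return List::create(_["vc_chain"] = vc_chain,
                      _["beta_chain"] = beta_chain,
                      _["a_mean"] = a_mean,
                      _["a_sd"] = a_sd,
                      _["retained"] = kept,
                      _["pd_failures"] = pd_failures);
}
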