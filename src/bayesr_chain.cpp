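// Gibbs sampler core for the extended BayesR model
//   y = Xb + Za + Wv + e,  e ~ N(0, E sigma2_e),  E = diag(1/w_i)
// with a K-component normal-mixture prior on each SNP effect
// (component variances mult[k] * sigma2_a2, first multiplier 0 = point mass),
// Dirichlet-updated mixture proportions, jointly sampled fixed effects and a
// single-site pedigree polygenic term. Uses R's RNG so chains are
// reproducible from set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::uvec r_permutation(int m) {
  arma::uvec p(m);
  for (int i = 0; i < m; ++i) p[i] = i;
  for (int i = m - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// [[Rcpp::export]]
List bayesr_chain_cpp(const arma::vec& y, const arma::mat& X,
                      const arma::mat& W, const arma::ivec& zidx,
                      const arma::sp_mat& Ainv, const arma::vec& wgt,
                      const arma::vec& mult, const arma::vec& alpha,
                      double sigma2_a2, int n_iter, int burn_in,
                      bool update_pr, arma::vec pr, bool permute_snps,
                      int refresh_every) {
  const int n = y.n_elem, p = X.n_cols, m = W.n_cols;
  const int q = Ainv.n_rows;
  const int K = mult.n_elem;
  const bool has_poly = q > 0;
  const double vary = arma::var(y);

  // state
  arma::vec b(p, arma::fill::zeros);
  arma::vec a(q, arma::fill::zeros);
  arma::vec v(m, arma::fill::zeros);
  arma::ivec comp(m, arma::fill::zeros);
  double sigma2_e = vary > 0 ? vary / 2.0 : 1.0;
  double sigma2_a = sigma2_a2 > 0 ? sigma2_a2 : 1.0;

  arma::vec e = y - X * b;              // residual cache (a = 0, v = 0)
  arma::vec ew = wgt % e;               // E^-1 e cache

  // fixed precomputations
  arma::mat XtWX = X.t() * (X.each_col() % wgt);
  arma::vec cj(m);                      // sum_i w_i W_ij^2
  for (int j = 0; j < m; ++j) cj[j] = arma::dot(wgt % W.col(j), W.col(j));

  // records per pedigree animal
  std::vector<std::vector<int>> recs(q);
  arma::vec sumw(q, arma::fill::zeros);
  if (has_poly) {
    for (int i = 0; i < n; ++i) {
      int zi = zidx[i];
      if (zi > 0) {
        recs[zi - 1].push_back(i);
        sumw[zi - 1] += wgt[i];
      }
    }
  }

  // accumulators (post burn-in)
  arma::vec v_sum(m, arma::fill::zeros), b_sum(p, arma::fill::zeros);
  arma::vec a_sum(q, arma::fill::zeros), pr_sum(K, arma::fill::zeros);
  arma::vec count_sum(K, arma::fill::zeros);
  arma::mat incl(m, K, arma::fill::zeros);
  double s2e_sum = 0.0, s2a_sum = 0.0;
  arma::vec s2e_trace(n_iter), s2a_trace(n_iter);
  int kept = 0;
  double drift_max = 0.0;

  arma::vec logL(K), beta(K), s2k(K), vjk(K);
  for (int k = 0; k < K; ++k) s2k[k] = mult[k] * sigma2_a2;

  for (int it = 1; it <= n_iter; ++it) {
    // 1. error variance: sigma2_e = e' E^-1 e / chisq_{n-2}
    double S = arma::dot(ew, e);
    if (!std::isfinite(S) || S < 0)
      stop("numerical corruption: e'E^-1 e = %f at iteration %d", S, it);
    sigma2_e = S / R::rchisq((double)(n - 2));
    if (vary > 0 && sigma2_e > 1e6 * vary)
      stop("divergence: sampled sigma2_e (%g) exceeds 1e6 x phenotypic "
           "variance at iteration %d", sigma2_e, it);

    // 2. fixed effects, joint block draw: N([X'R^-1X]^-1 X'R^-1 y*, [X'R^-1X]^-1)
    {
      arma::vec rhs = X.t() * (ew + wgt % (X * b)) / sigma2_e;
      arma::mat M = XtWX / sigma2_e;
      arma::mat U = arma::chol(M);
      arma::vec mean = arma::solve(M, rhs, arma::solve_opts::likely_sympd);
      arma::vec z(p);
      for (int i = 0; i < p; ++i) z[i] = norm_rand();
      arma::vec b_new = mean + arma::solve(arma::trimatu(U), z);
      arma::vec de = X * (b - b_new);
      e += de;
      ew += wgt % de;
      b = b_new;
    }

    if (has_poly) {
      // 3. polygenic effects, single-site loop
      double inv_sa = 1.0 / sigma2_a;
      for (int i = 0; i < q; ++i) {
        double zRy = 0.0;
        for (int r : recs[i]) zRy += wgt[r] * (e[r] + a[i]);
        zRy /= sigma2_e;
        // Ainv is symmetric: iterate its (sparse) column i for the row dot
        double off = 0.0, adiag = 0.0;
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(i);
             it != Ainv.end_col(i); ++it) {
          if ((int)it.row() == i) adiag = *it;
          else off += (*it) * a[it.row()];
        }
        double lhs = sumw[i] / sigma2_e + adiag * inv_sa;
        double mean = (zRy - off * inv_sa) / lhs;
        double a_new = mean + norm_rand() / std::sqrt(lhs);
        double da = a[i] - a_new;
        if (da != 0.0) {
          for (int r : recs[i]) {
            e[r] += da;
            ew[r] += wgt[r] * da;
          }
        }
        a[i] = a_new;
      }
      // 4. polygenic variance: a' A^-1 a / chisq_{q-2}
      double Sa = arma::dot(a, Ainv * a);
      if (!std::isfinite(Sa) || Sa < 0)
        stop("numerical corruption: a'A^-1 a = %f at iteration %d", Sa, it);
      sigma2_a = Sa / R::rchisq((double)(q - 2));
      if (sigma2_a <= 0 || !std::isfinite(sigma2_a))
        sigma2_a = 1e-10 * (vary > 0 ? vary : 1.0);
    }

    // 5. SNP effects: sample component then effect, marker order permuted
    beta.zeros();
    arma::uvec ord = permute_snps ? r_permutation(m) : arma::regspace<arma::uvec>(0, m - 1);
    for (int jj = 0; jj < m; ++jj) {
      int j = ord[jj];
      double wRw = cj[j] / sigma2_e;
      double rhs = arma::dot(W.col(j), ew) / sigma2_e + wRw * v[j];
      double maxL = R_NegInf;
      for (int k = 0; k < K; ++k) {
        if (pr[k] <= 0.0) {
          logL[k] = R_NegInf;
          vjk[k] = 0.0;
          continue;
        }
        if (s2k[k] <= 0.0) {
          vjk[k] = 0.0;
          logL[k] = std::log(pr[k]);
        } else {
          double denom = wRw + 1.0 / s2k[k];
          vjk[k] = rhs / denom;
          logL[k] = -0.5 * (std::log1p(wRw * s2k[k]) - rhs * vjk[k]) +
            std::log(pr[k]);
        }
        if (logL[k] > maxL) maxL = logL[k];
      }
      if (!std::isfinite(maxL))
        stop("non-finite component score for marker %d at iteration %d",
             j + 1, it);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        logL[k] = std::isfinite(logL[k]) ? std::exp(logL[k] - maxL) : 0.0;
        tot += logL[k];
      }
      double u = unif_rand() * tot;
      int k = 0;
      double cum = logL[0];
      while (cum < u && k < K - 1) cum += logL[++k];
      double v_new;
      if (s2k[k] <= 0.0) {
        v_new = 0.0;
      } else {
        double denom = wRw + 1.0 / s2k[k];
        v_new = vjk[k] + norm_rand() / std::sqrt(denom);
      }
      comp[j] = k;
      beta[k] += 1.0;
      double dv = v[j] - v_new;
      if (dv != 0.0) {
        e += W.col(j) * dv;
        ew += (wgt % W.col(j)) * dv;
        v[j] = v_new;
      }
    }

    // 6. mixture proportions: pr ~ Dirichlet(alpha + beta)
    if (update_pr) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        pr[k] = R::rgamma(alpha[k] + beta[k], 1.0);
        tot += pr[k];
      }
      pr /= tot;
    }

    // periodic full residual recompute bounds float drift
    if (refresh_every > 0 && it % refresh_every == 0) {
      arma::vec e_true = y - X * b - W * v;
      if (has_poly)
        for (int i = 0; i < q; ++i)
          for (int r : recs[i]) e_true[r] -= a[i];
      double drift = arma::abs(e - e_true).max();
      if (drift > drift_max) drift_max = drift;
      e = e_true;
      ew = wgt % e;
    }

    s2e_trace[it - 1] = sigma2_e;
    s2a_trace[it - 1] = sigma2_a;
    if (it > burn_in) {
      ++kept;
      v_sum += v;
      b_sum += b;
      if (has_poly) a_sum += a;
      s2e_sum += sigma2_e;
      s2a_sum += sigma2_a;
      pr_sum += pr;
      count_sum += beta;
      for (int j = 0; j < m; ++j) incl(j, comp[j]) += 1.0;
    }
  }

  if (kept == 0) stop("no post burn-in iterations (n_iter <= burn_in)");
  return List::create(
    _["v_mean"] = v_sum / kept, _["b_mean"] = b_sum / kept,
    _["a_mean"] = a_sum / kept, _["sigma2_e_mean"] = s2e_sum / kept,
    _["sigma2_a_mean"] = s2a_sum / kept, _["pr_mean"] = pr_sum / kept,
    _["count_mean"] = count_sum / kept, _["incl_freq"] = incl / kept,
    _["sigma2_e_trace"] = s2e_trace, _["sigma2_a_trace"] = s2a_trace,
    _["resid_drift_max"] = drift_max, _["n_kept"] = kept);
}
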