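#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive single-site Metropolis-within-Gibbs sampler for the Poisson
// convolution (BYM) model:
//   O_i ~ Poisson(lambda_i E_i),  log lambda_i = alpha + x_i'beta + S_i + H_i
// S: intrinsic CAR (pairwise-difference prior, each edge once), recentred to
// sum-to-zero per connected component after every sweep (constant absorbed
// into alpha); H: iid N(0, sigma_H^2); alpha flat; beta_k ~ N(0, v_beta);
// sigma_S, sigma_H ~ U(0, sigma_upper) on the standard-deviation scale.
//
// Random-walk proposals per block, step sizes adapted during burn-in only
// toward `target_accept`. Uses R's RNG so chains are reproducible from
// set.seed() on the R side.

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List run_mcmc_cpp(IntegerVector O, NumericVector E, NumericMatrix X,
                  List nbr_list, IntegerVector comp, int n_comp,
                  bool include_spatial, bool include_het,
                  double prior_beta_var, double sigma_upper,
                  int n_iter, int burn_in, int thin,
                  int adapt_window, double target_accept,
                  double alpha0, NumericVector beta0,
                  NumericVector S0, NumericVector H0,
                  double sigmaS0, double sigmaH0,
                  bool use_likelihood) {
  const int n = O.size();
  const int p = X.ncol();

  std::vector< std::vector<int> > nbr(n);
  int n_edges = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbr_list[i];
    nbr[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < nbr[i].size(); ++k) nbr[i][k] -= 1; // 1- to 0-based
    n_edges += nbr[i].size();
  }
  n_edges /= 2;
  const int icar_rank = n - n_comp;

  // state
  double alpha = alpha0, sigmaS = sigmaS0, sigmaH = sigmaH0;
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> H(H0.begin(), H0.end());

  // cached linear predictor and Poisson mean
  std::vector<double> eta(n), lamE(n), logE(n), lgamO(n);
  double sumO = 0.0;
  std::vector<double> OX(p, 0.0);
  for (int i = 0; i < n; ++i) {
    logE[i] = std::log(E[i]);
    lgamO[i] = std::lgamma((double)O[i] + 1.0);
    sumO += O[i];
    for (int k = 0; k < p; ++k) OX[k] += O[i] * X(i, k);
  }
  auto refresh_eta = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = alpha + S[i] + H[i];
      for (int k = 0; k < p; ++k) e += X(i, k) * beta[k];
      eta[i] = e;
      lamE[i] = use_likelihood ? E[i] * std::exp(e) : 0.0;
    }
  };
  refresh_eta();

  auto full_loglik = [&]() {
    if (!use_likelihood) return 0.0;
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      ll += O[i] * (eta[i] + logE[i]) - lamE[i] - lgamO[i];
    return ll;
  };
  auto icar_quad = [&]() { // sum over edges (i<j) of (S_i - S_j)^2
    double q = 0.0;
    for (int i = 0; i < n; ++i)
      for (size_t k = 0; k < nbr[i].size(); ++k) {
        int j = nbr[i][k];
        if (j > i) q += sq(S[i] - S[j]);
      }
    return q;
  };

  // proposal step sizes and acceptance bookkeeping; blocks:
  // 0 alpha, 1..p beta_k, p+1 S, p+2 H, p+3 sigmaS, p+4 sigmaH
  const int n_blocks = p + 5;
  std::vector<double> step(n_blocks, 0.1);
  step[0] = 0.1;
  for (int k = 0; k < p; ++k) {
    // scale beta proposals to the covariate scale
    double sx = 0.0, mx = 0.0;
    for (int i = 0; i < n; ++i) mx += X(i, k);
    mx /= n;
    for (int i = 0; i < n; ++i) sx += sq(X(i, k) - mx);
    sx = std::sqrt(sx / std::max(1, n - 1));
    step[1 + k] = (sx > 1e-12 && use_likelihood) ? 0.1 / sx
                                                 : std::sqrt(prior_beta_var);
  }
  step[p + 1] = 0.3; step[p + 2] = 0.3; step[p + 3] = 0.1; step[p + 4] = 0.1;
  std::vector<long> win_acc(n_blocks, 0), win_try(n_blocks, 0);
  std::vector<long> tot_acc(n_blocks, 0), tot_try(n_blocks, 0);

  auto mh_count = [&](int b, bool accepted, bool adapting) {
    win_try[b]++; if (accepted) win_acc[b]++;
    if (!adapting) { tot_try[b]++; if (accepted) tot_acc[b]++; }
  };

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 1 + p + 2 * n + 3);
  int row = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= burn_in;

    // ---- alpha (flat prior; skipped when likelihood is off) ----
    if (use_likelihood) {
      double d = R::norm_rand() * step[0];
      double sumLamE = 0.0;
      for (int i = 0; i < n; ++i) sumLamE += lamE[i];
      double dll = sumO * d - (std::exp(d) - 1.0) * sumLamE;
      bool acc = std::log(R::unif_rand()) < dll;
      if (acc) {
        alpha += d;
        double m = std::exp(d);
        for (int i = 0; i < n; ++i) { eta[i] += d; lamE[i] *= m; }
      }
      mh_count(0, acc, adapting);
    }

    // ---- beta ----
    for (int k = 0; k < p; ++k) {
      double d = R::norm_rand() * step[1 + k];
      double dll = 0.0;
      if (use_likelihood) {
        dll = d * OX[k];
        for (int i = 0; i < n; ++i)
          dll -= lamE[i] * (std::exp(d * X(i, k)) - 1.0);
      }
      double b0 = beta[k], b1 = beta[k] + d;
      double dlp = -(sq(b1) - sq(b0)) / (2.0 * prior_beta_var);
      bool acc = R_finite(dll) && std::log(R::unif_rand()) < dll + dlp;
      if (acc) {
        beta[k] = b1;
        if (use_likelihood)
          for (int i = 0; i < n; ++i) {
            eta[i] += d * X(i, k);
            lamE[i] *= std::exp(d * X(i, k));
          }
      }
      mh_count(1 + k, acc, adapting);
    }

    // ---- S (single-site) ----
    if (include_spatial) {
      double inv2s2 = 1.0 / (2.0 * sq(sigmaS));
      for (int i = 0; i < n; ++i) {
        if (nbr[i].empty()) continue; // pinned island
        // proposal scale tracks the current field sd so acceptance stays
        // stable while sigma_S traverses its (wide) posterior
        double d = R::norm_rand() * step[p + 1] * sigmaS;
        double dll = use_likelihood
          ? O[i] * d - lamE[i] * (std::exp(d) - 1.0) : 0.0;
        double nsum = 0.0;
        for (size_t kk = 0; kk < nbr[i].size(); ++kk) nsum += S[nbr[i][kk]];
        double deg = (double)nbr[i].size();
        double dlp = -inv2s2 * (deg * (2.0 * S[i] * d + sq(d)) - 2.0 * d * nsum);
        bool acc = std::log(R::unif_rand()) < dll + dlp;
        if (acc) {
          S[i] += d;
          if (use_likelihood) { eta[i] += d; lamE[i] *= std::exp(d); }
        }
        mh_count(p + 1, acc, adapting);
      }
    }

    // ---- H (single-site) ----
    if (include_het) {
      double inv2h2 = 1.0 / (2.0 * sq(sigmaH));
      for (int i = 0; i < n; ++i) {
        double d = R::norm_rand() * step[p + 2] * sigmaH;
        double dll = use_likelihood
          ? O[i] * d - lamE[i] * (std::exp(d) - 1.0) : 0.0;
        double dlp = -inv2h2 * (2.0 * H[i] * d + sq(d));
        bool acc = std::log(R::unif_rand()) < dll + dlp;
        if (acc) {
          H[i] += d;
          if (use_likelihood) { eta[i] += d; lamE[i] *= std::exp(d); }
        }
        mh_count(p + 2, acc, adapting);
      }
    }

    // ---- sigma_S: exact draw from the truncated inverse-gamma full
    // conditional.  Target on the sd scale (uniform prior):
    //   p(sigma | S) ~ sigma^{-rank} exp(-q / (2 sigma^2)),  0 < sigma <= u,
    // so with tau = sigma^2, X = (q/2)/tau ~ Gamma((rank-1)/2, 1) truncated
    // to X >= (q/2)/u^2; sampled by inverse CDF.  Falls back to a
    // random-walk step when the Gamma shape is not positive (rank <= 1).
    if (include_spatial) {
      double q = icar_quad();
      double a = (icar_rank - 1.0) / 2.0;
      if (a > 0.0 && q > 0.0) {
        double b = q / 2.0;
        double xmin = b / sq(sigma_upper);
        double p0 = R::pgamma(xmin, a, 1.0, 1, 0);
        double u = p0 + R::unif_rand() * (1.0 - p0);
        if (u >= 1.0) u = 1.0 - 1e-16;
        double x = R::qgamma(u, a, 1.0, 1, 0);
        if (x < xmin) x = xmin;
        sigmaS = std::sqrt(b / x);
        if (sigmaS > sigma_upper) sigmaS = sigma_upper;
      } else {
        double d = R::norm_rand() * step[p + 3];
        double s1 = sigmaS + d;
        bool acc = false;
        if (s1 > 0.0 && s1 <= sigma_upper) {
          double lt0 = -icar_rank * std::log(sigmaS) - q / (2.0 * sq(sigmaS));
          double lt1 = -icar_rank * std::log(s1) - q / (2.0 * sq(s1));
          acc = std::log(R::unif_rand()) < lt1 - lt0;
          if (acc) sigmaS = s1;
        }
        mh_count(p + 3, acc, adapting);
      }
    }

    // ---- sigma_H: same construction with shape (n-1)/2 ----
    if (include_het) {
      double sh2 = 0.0;
      for (int i = 0; i < n; ++i) sh2 += sq(H[i]);
      double a = (n - 1.0) / 2.0;
      if (a > 0.0 && sh2 > 0.0) {
        double b = sh2 / 2.0;
        double xmin = b / sq(sigma_upper);
        double p0 = R::pgamma(xmin, a, 1.0, 1, 0);
        double u = p0 + R::unif_rand() * (1.0 - p0);
        if (u >= 1.0) u = 1.0 - 1e-16;
        double x = R::qgamma(u, a, 1.0, 1, 0);
        if (x < xmin) x = xmin;
        sigmaH = std::sqrt(b / x);
        if (sigmaH > sigma_upper) sigmaH = sigma_upper;
      } else {
        double d = R::norm_rand() * step[p + 4];
        double s1 = sigmaH + d;
        bool acc = false;
        if (s1 > 0.0 && s1 <= sigma_upper) {
          double lt0 = -n * std::log(sigmaH) - sh2 / (2.0 * sq(sigmaH));
          double lt1 = -n * std::log(s1) - sh2 / (2.0 * sq(s1));
          acc = std::log(R::unif_rand()) < lt1 - lt0;
          if (acc) sigmaH = s1;
        }
        mh_count(p + 4, acc, adapting);
      }
    }

    // ---- recenter S per component, constant into alpha ----
    if (include_spatial) {
      std::vector<double> msum(n_comp, 0.0);
      std::vector<int> mcnt(n_comp, 0);
      for (int i = 0; i < n; ++i) {
        if (nbr[i].empty()) continue;
        msum[comp[i] - 1] += S[i];
        mcnt[comp[i] - 1] += 1;
      }
      double shift = 0.0;
      for (int i = 0; i < n; ++i) {
        if (nbr[i].empty()) continue;
        double m = msum[comp[i] - 1] / mcnt[comp[i] - 1];
        S[i] -= m;
        shift += m;
      }
      if (use_likelihood) alpha += shift / n;
      refresh_eta();
    }

    // ---- adapt step sizes during burn-in ----
    if (adapting && it % adapt_window == 0) {
      for (int b = 0; b < n_blocks; ++b) {
        if (win_try[b] == 0) continue;
        double rate = (double)win_acc[b] / (double)win_try[b];
        step[b] *= std::exp(rate - target_accept);
        if (step[b] < 1e-6) step[b] = 1e-6;
        if (step[b] > 1e4) step[b] = 1e4;
        win_acc[b] = 0; win_try[b] = 0;
      }
    }

    // ---- store ----
    if (it > burn_in && (it - burn_in) % thin == 0 && row < n_keep) {
      int c = 0;
      draws(row, c++) = alpha;
      for (int k = 0; k < p; ++k) draws(row, c++) = beta[k];
      for (int i = 0; i < n; ++i) draws(row, c++) = S[i];
      for (int i = 0; i < n; ++i) draws(row, c++) = H[i];
      draws(row, c++) = sigmaS;
      draws(row, c++) = sigmaH;
      draws(row, c++) = full_loglik();
      ++row;
    }
  }

  NumericVector acc_rate(n_blocks), steps(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    acc_rate[b] = tot_try[b] > 0 ? (double)tot_acc[b] / (double)tot_try[b]
                                 : NA_REAL;
    steps[b] = step[b];
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["step_size"] = steps, _["n_edges"] = n_edges);
}
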