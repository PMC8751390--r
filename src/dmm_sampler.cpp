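#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// Dirichlet-multinomial model.
//
// Each group g has its own Dirichlet parameter vector alpha_g = theta_g *
// pi_g; the replicate-level multinomial proportions are integrated out
// analytically, so the likelihood of group g's replicates is a product of
// Dirichlet-multinomial pmfs with parameter alpha_g.  Sampling is done on
// u = log(alpha) (one unconstrained coordinate per taxon per group), which
// makes a single-coordinate update O(n_g) Gamma-function evaluations:
// only alpha_k and the total A = sum(alpha) change.
//
// Priors (on the constrained scale): pi_g ~ Dirichlet(c, ..., c),
// theta_g ~ half-Cauchy(scale).  The change of variables (pi, theta) ->
// alpha contributes A^-(K-1); sampling on log alpha adds sum(log alpha).
// Collecting terms, the log prior + Jacobians equal
//   sum_i c*log(alpha_i) - (K*c - 1)*log(A) - log(1 + (A/scale)^2)
// up to constants.

static inline double log_half_cauchy(double A, double scale) {
  double z = A / scale;
  return -std::log1p(z * z);
}

// [[Rcpp::export]]
List dmm_mcmc_cpp(NumericMatrix counts, IntegerVector group, int n_group,
                  int n_chains, int n_burn, int n_keep,
                  double prior_conc, double theta_scale,
                  double init_step, double target_accept) {
  const int n = counts.nrow(), K = counts.ncol(), G = n_group;
  if (n_chains < 1 || n_keep < 1 || n_burn < 0)
    stop("invalid chain settings");

  // per-group replicate rows and depths
  std::vector<std::vector<int>> rows(G);
  for (int j = 0; j < n; ++j) {
    int g = group[j];
    if (g < 0 || g >= G) stop("group index out of range");
    rows[g].push_back(j);
  }
  std::vector<std::vector<double>> depth(G);
  for (int g = 0; g < G; ++g) {
    if (rows[g].empty()) stop("a group has no replicates");
    for (int j : rows[g]) {
      double d = 0.0;
      for (int k = 0; k < K; ++k) d += counts(j, k);
      depth[g].push_back(d);
    }
  }
  // nonzero counts per (g, k)
  std::vector<std::vector<std::vector<double>>> nz(G,
      std::vector<std::vector<double>>(K));
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < K; ++k)
      for (int j : rows[g]) {
        double x = counts(j, k);
        if (x > 0) nz[g][k].push_back(x);
      }

  const double la_min = -30.0, la_max = 30.0;
  const double kc1 = K * prior_conc - 1.0;

  NumericVector pi_draws((R_xlen_t)n_chains * n_keep * G * K);
  pi_draws.attr("dim") = IntegerVector::create(n_chains, n_keep, G, K);
  NumericVector theta_draws((R_xlen_t)n_chains * n_keep * G);
  theta_draws.attr("dim") = IntegerVector::create(n_chains, n_keep, G);
  NumericMatrix accept_rate(n_chains, G * K);
  NumericMatrix step_out(n_chains, G * K);

  // empirical group proportions for initialization
  std::vector<std::vector<double>> phat(G, std::vector<double>(K));
  for (int g = 0; g < G; ++g) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.5;  // pseudocount keeps all-zero taxa interior
      for (int j : rows[g]) s += counts(j, k);
      phat[g][k] = s;
      tot += s;
    }
    for (int k = 0; k < K; ++k) phat[g][k] /= tot;
  }

  auto depth_term = [&](int g, double A) {
    double s = rows[g].size() * std::lgamma(A);
    for (double d : depth[g]) s -= std::lgamma(A + d);
    return s;
  };
  auto taxon_term = [&](int g, int k, double a) {
    double s = -(double)nz[g][k].size() * std::lgamma(a);
    for (double x : nz[g][k]) s += std::lgamma(a + x);
    return s;
  };

  const int n_iter = n_burn + n_keep;
  for (int ch = 0; ch < n_chains; ++ch) {
    // overdispersed init around the empirical proportions
    std::vector<std::vector<double>> la(G, std::vector<double>(K));
    std::vector<double> A(G), dterm(G);
    std::vector<std::vector<double>> tterm(G, std::vector<double>(K));
    std::vector<std::vector<double>> lstep(G,
        std::vector<double>(K, std::log(init_step)));
    std::vector<std::vector<int>> acc(G, std::vector<int>(K, 0));
    std::vector<double> lstep_scale(G, std::log(init_step));

    for (int g = 0; g < G; ++g) {
      double theta0 = std::exp(std::log(300.0) + norm_rand());
      double As = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = theta0 * phat[g][k] * std::exp(0.4 * norm_rand());
        la[g][k] = std::min(std::max(std::log(a), la_min), la_max);
        As += std::exp(la[g][k]);
      }
      A[g] = As;
      dterm[g] = depth_term(g, As);
      for (int k = 0; k < K; ++k)
        tterm[g][k] = taxon_term(g, k, std::exp(la[g][k]));
    }

    for (int it = 0; it < n_iter; ++it) {
      bool adapting = it < n_burn;
      double gam = 1.0 / std::pow(it + 10.0, 0.6);
      for (int g = 0; g < G; ++g) {
        for (int k = 0; k < K; ++k) {
          double cur = la[g][k], a = std::exp(cur);
          double prop = cur + std::exp(lstep[g][k]) * norm_rand();
          bool accepted = false;
          if (prop >= la_min && prop <= la_max) {
            double a2 = std::exp(prop);
            double A2 = A[g] - a + a2;
            double d2 = depth_term(g, A2);
            double t2 = taxon_term(g, k, a2);
            double lr = (d2 - dterm[g]) + (t2 - tterm[g][k])
              + prior_conc * (prop - cur)
              - kc1 * (std::log(A2) - std::log(A[g]))
              + log_half_cauchy(A2, theta_scale)
              - log_half_cauchy(A[g], theta_scale);
            if (std::log(unif_rand()) < lr) {
              la[g][k] = prop;
              A[g] = A2;
              dterm[g] = d2;
              tterm[g][k] = t2;
              accepted = true;
            }
          }
          if (adapting) {
            lstep[g][k] += gam * ((accepted ? 1.0 : 0.0) - target_accept);
            if (lstep[g][k] < -8.0) lstep[g][k] = -8.0;
            if (lstep[g][k] > 4.0) lstep[g][k] = 4.0;
          } else if (accepted) {
            acc[g][k] += 1;
          }
        }
      }
      // whole-group scale move: shifts every log alpha_k by the same eps,
      // i.e. updates theta_g with pi_g held fixed; decorrelates the
      // intensity from the slow sum-of-coordinates random walk
      for (int g = 0; g < G; ++g) {
        double eps = std::exp(lstep_scale[g]) * norm_rand();
        bool accepted = false;
        double lo = la_min, hi = la_max;
        for (int k = 0; k < K; ++k) {
          lo = std::min(lo, la[g][k] + eps);
          hi = std::max(hi, la[g][k] + eps);
        }
        if (lo >= la_min && hi <= la_max) {
          double A2 = A[g] * std::exp(eps);
          double d2 = depth_term(g, A2);
          double tsum_old = 0.0, tsum_new = 0.0;
          std::vector<double> t2(K);
          for (int k = 0; k < K; ++k) {
            tsum_old += tterm[g][k];
            t2[k] = taxon_term(g, k, std::exp(la[g][k] + eps));
            tsum_new += t2[k];
          }
          double lr = (d2 - dterm[g]) + (tsum_new - tsum_old)
            + prior_conc * K * eps
            - kc1 * (std::log(A2) - std::log(A[g]))
            + log_half_cauchy(A2, theta_scale)
            - log_half_cauchy(A[g], theta_scale);
          if (std::log(unif_rand()) < lr) {
            for (int k = 0; k < K; ++k) la[g][k] += eps;
            A[g] = A2;
            dterm[g] = d2;
            tterm[g] = t2;
            accepted = true;
          }
        }
        if (adapting) {
          lstep_scale[g] += gam * ((accepted ? 1.0 : 0.0) - target_accept);
          if (lstep_scale[g] < -8.0) lstep_scale[g] = -8.0;
          if (lstep_scale[g] > 4.0) lstep_scale[g] = 4.0;
        }
      }
      // periodic exact refresh of cached sums against FP drift
      if ((it + 1) % 500 == 0) {
        for (int g = 0; g < G; ++g) {
          double As = 0.0;
          for (int k = 0; k < K; ++k) As += std::exp(la[g][k]);
          A[g] = As;
          dterm[g] = depth_term(g, As);
        }
      }
      if (!adapting) {
        int keep = it - n_burn;
        for (int g = 0; g < G; ++g) {
          double As = A[g];
          theta_draws[ch + n_chains * (keep + n_keep * g)] = As;
          for (int k = 0; k < K; ++k) {
            pi_draws[ch + n_chains * (keep + n_keep * (g + G * k))] =
              std::exp(la[g][k]) / As;
          }
        }
      }
    }
    for (int g = 0; g < G; ++g)
      for (int k = 0; k < K; ++k) {
        accept_rate(ch, g * K + k) = (double)acc[g][k] / n_keep;
        step_out(ch, g * K + k) = std::exp(lstep[g][k]);
      }
  }

  return List::create(_["pi"] = pi_draws, _["theta"] = theta_draws,
                      _["accept_rate"] = accept_rate, _["step"] = step_out);
}
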