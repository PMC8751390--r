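# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: beta-binomial via lchoose/lbeta, grid posteriors
# via direct summation, Welch/Tukey via their textbook closed forms.

# beta-binomial log pmf, BB(x; n, a, b)
bb_log_pmf <- function(x, n, a, b) {
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

half_cauchy_log <- function(theta, scale) {
  log(2 / (pi * scale)) - log1p((theta / scale)^2)
}

# Brute-force grid posterior of pi_1 for a single group of K = 2 samples,
# flat Dirichlet(1) prior on pi and half-Cauchy(theta_scale) prior on theta
# marginalised over a log-spaced theta grid.  counts: n x 2 matrix.
grid_posterior_k2 <- function(counts, n_grid = 10000, theta_scale = 100,
                              theta_range = c(0.5, 1e5), n_theta = 600) {
  p <- (seq_len(n_grid) - 0.5) / n_grid
  lth <- seq(log(theta_range[1]), log(theta_range[2]), length.out = n_theta)
  th <- exp(lth)
  w <- c(diff(lth)[1] / 2, diff(lth)) + c(diff(lth), diff(lth)[1] / 2) / 2
  w <- w[seq_len(n_theta)]  # trapezoid weights in log-theta
  d <- rowSums(counts)
  logpost <- matrix(0, n_grid, n_theta)
  for (t in seq_len(n_theta)) {
    ll <- 0
    for (j in seq_len(nrow(counts))) {
      ll <- ll + bb_log_pmf(counts[j, 1], d[j], th[t] * p, th[t] * (1 - p))
    }
    # theta jacobian for log grid + prior
    logpost[, t] <- ll + half_cauchy_log(th[t], theta_scale) + log(th[t]) +
      log(w[t])
  }
  m <- max(logpost)
  dens <- rowSums(exp(logpost - m))
  dens <- dens / sum(dens)
  list(p = p, dens = dens, cdf = cumsum(dens), mean = sum(p * dens))
}

# sup |empirical CDF of draws - grid CDF|
ks_vs_grid <- function(draws, grid) {
  cdf_at <- stats::approx(grid$p, grid$cdf, xout = sort(draws), rule = 2)$y
  n <- length(draws)
  max(abs(cdf_at - seq_len(n) / n), abs(cdf_at - (seq_len(n) - 1) / n))
}

# all count vectors of length k summing to n
enumerate_counts <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (x in 0:n) {
    rest <- enumerate_counts(n - x, k - 1)
    out[[length(out) + 1]] <- cbind(x, rest)
  }
  unname(do.call(rbind, out))
}

# Welch t statistic and df from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tukey adjusted p for one pairwise difference from the studentized range
tukey_oracle_p <- function(diff, mse, n_per_group, k_groups, df_err) {
  q <- abs(diff) / sqrt(mse / n_per_group)
  1 - ptukey(q, k_groups, df_err)
}

# a minimal dmm_fit with prescribed pooled draws (chains x draws x G x K)
fake_dmm_fit <- function(pi_draws, theta_draws = NULL,
                         groups = dimnames(pi_draws)[[3]],
                         taxa = NULL) {
  d <- dim(pi_draws)
  if (is.null(groups)) groups <- paste0("g", seq_len(d[3]))
  if (is.null(taxa)) taxa <- paste0("t", seq_len(d[4]))
  if (is.null(theta_draws)) {
    theta_draws <- array(100, dim = d[1:3])
  }
  structure(list(pi = pi_draws, theta = theta_draws, groups = groups,
                 taxa = taxa, accept_rate = matrix(0.4, d[1], d[3] * d[4]),
                 settings = dmm_settings(chains = max(d[1], 2), draws = d[2])),
            class = "dmm_fit")
}
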