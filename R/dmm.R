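#' Dirichlet-multinomial log-likelihood
#'
#' Log density of the Dirichlet-multinomial (compound multinomial)
#' distribution: the marginal likelihood of one sample's read counts when
#' the replicate-level multinomial proportions are Dirichlet-distributed
#' around the group composition, i.e. `counts ~ DM(theta * pi)`.  The
#' multinomial coefficient is included, so the density sums to one over all
#' count vectors of a given depth.
#'
#' @param counts a non-negative integer vector of length K, or a matrix with
#'   one sample per row (a vector of log densities is returned).
#' @param pi strictly positive composition vector of length K (sums to 1).
#' @param theta positive intensity (Dirichlet concentration scale); larger
#'   values mean replicate compositions hug `pi` more tightly.
#' @return log density (one value per sample).
#' @examples
#' dm_log_likelihood(c(3, 2, 0), pi = c(0.5, 0.3, 0.2), theta = 10)
#' @export
dm_log_likelihood <- function(counts, pi, theta) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(pi) != ncol(counts)) stop("length(pi) must match taxa", call. = FALSE)
  if (any(pi <= 0)) stop("pi must be strictly positive", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1", call. = FALSE)
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  alpha <- theta * pi
  d <- rowSums(counts)
  ll <- lgamma(d + 1) - rowSums(lgamma(counts + 1)) +
    lgamma(theta) - lgamma(theta + d) +
    rowSums(lgamma(sweep(counts, 2, alpha, "+"))) - sum(lgamma(alpha))
  if (any(!is.finite(ll))) stop("non-finite log-likelihood", call. = FALSE)
  unname(ll)
}

#' Hierarchical-model log posterior
#'
#' Unnormalised log posterior of the Dirichlet-multinomial hierarchy: the
#' sum of [dm_log_likelihood()] over replicates in each group, a symmetric
#' Dirichlet prior on each group composition, and a half-Cauchy prior on
#' each group intensity.  With `include_jacobian = TRUE` the log Jacobians
#' of the sampling transform (one log-alpha coordinate per taxon, with
#' `alpha = theta * pi`) are added, giving the density the MCMC sampler
#' actually explores.
#'
#' @param pi matrix of group compositions (groups x taxa, rows sum to 1,
#'   strictly positive).
#' @param theta positive intensity, one per group (recycled if scalar).
#' @param counts count matrix (samples x taxa).
#' @param groups integer or factor of group membership per sample; levels
#'   align with the rows of `pi`.
#' @param prior_conc symmetric Dirichlet concentration (default 1 = flat on
#'   the simplex).
#' @param theta_scale half-Cauchy scale for the intensity prior.
#' @param include_jacobian add the log-alpha change-of-variable terms.
#' @return scalar log density.
#' @export
log_posterior <- function(pi, theta, counts, groups, prior_conc = 1,
                          theta_scale = 100, include_jacobian = FALSE) {
  pi <- rbind(pi)
  G <- nrow(pi)
  theta <- rep_len(theta, G)
  gi <- as.integer(factor(groups, levels = if (is.factor(groups)) levels(groups) else unique(groups)))
  counts <- as.matrix(counts)
  if (any(pi <= 0)) stop("non-finite log posterior: pi has non-positive entries", call. = FALSE)
  if (any(theta <= 0)) stop("non-finite log posterior: theta not positive", call. = FALSE)
  ll <- 0
  if (nrow(counts) > 0) {
    for (g in seq_len(G)) {
      rows <- which(gi == g)
      if (length(rows) > 0) {
        ll <- ll + sum(dm_log_likelihood(counts[rows, , drop = FALSE], pi[g, ], theta[g]))
      }
    }
  }
  K <- ncol(pi)
  lp_pi <- sum((prior_conc - 1) * log(pi)) +
    G * (lgamma(K * prior_conc) - K * lgamma(prior_conc))
  lp_theta <- sum(-log1p((theta / theta_scale)^2)) + G * log(2 / (pi_const() * theta_scale))
  out <- ll + lp_pi + lp_theta
  if (include_jacobian) {
    # (pi, theta) -> alpha contributes -(K-1) log theta; log-alpha sampling
    # adds sum(log alpha)
    alpha <- sweep(pi, 1, theta, "*")
    out <- out - (K - 1) * sum(log(theta)) + sum(log(alpha))
  }
  if (!is.finite(out)) {
    part <- c(likelihood = ll, pi_prior = lp_pi, theta_prior = lp_theta)
    stop("non-finite log posterior (", paste(names(part)[!is.finite(part)], collapse = ", "),
         ")", call. = FALSE)
  }
  out
}

pi_const <- function() base::pi

#' MCMC settings for the Dirichlet-multinomial model
#'
#' @param chains number of chains (>= 2 so convergence can be diagnosed).
#' @param burn_in adaptation/warm-up sweeps discarded per chain.
#' @param draws retained sweeps per chain (defaults give 4 x 1000 = 4000
#'   retained posterior draws).
#' @param seed integer seed; all chains are reproducible from it.
#' @param level credible level for the posterior-difference decision rule.
#' @param prior_conc symmetric Dirichlet prior concentration on each group
#'   composition.
#' @param theta_scale half-Cauchy prior scale on the intensity.
#' @param init_step initial random-walk step size (adapted during burn-in).
#' @param target_accept coordinate-wise acceptance target for adaptation.
#' @return a `dmm_settings` list.
#' @export
dmm_settings <- function(chains = 4, burn_in = 1500, draws = 1000, seed = 1L,
                         level = 0.95, prior_conc = 1, theta_scale = 100,
                         init_step = 0.2, target_accept = 0.44) {
  stopifnot(chains >= 2, draws >= 1, burn_in >= 0, level > 0, level < 1,
            prior_conc > 0, theta_scale > 0)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 draws = as.integer(draws), seed = as.integer(seed),
                 level = level, prior_conc = prior_conc,
                 theta_scale = theta_scale, init_step = init_step,
                 target_accept = target_accept),
            class = "dmm_settings")
}

#' Fit the hierarchical Dirichlet-multinomial model
#'
#' Samples the posterior of the group compositions `pi_g` and intensities
#' `theta_g` by adaptive Metropolis-within-Gibbs on unconstrained log-alpha
#' coordinates (`alpha_g = theta_g * pi_g`), with adaptation frozen at the
#' end of burn-in.  The replicate-level multinomial proportions are
#' marginalised analytically (Dirichlet-multinomial likelihood), so no
#' latent per-sample compositions are sampled.  No rarefaction is applied:
#' unequal sequencing depths enter the likelihood as-is.
#'
#' @param ct a count table tibble.
#' @param groups group label per sample: either a vector aligned with
#'   `ct$sample_id` or a named vector keyed by sample id.  Samples with
#'   `NA` group are excluded.
#' @param settings a [dmm_settings()] object.
#' @return a `dmm_fit` object: posterior draw arrays `pi`
#'   (chains x draws x groups x taxa) and `theta` (chains x draws x
#'   groups), group levels, taxon ids, acceptance rates, and the settings.
#' @export
fit_dmm <- function(ct, groups, settings = dmm_settings()) {
  validate_count_table(ct, require_positive_depth = TRUE)
  m <- count_matrix(ct)
  if (!is.null(names(groups))) groups <- groups[ct$sample_id]
  if (length(groups) != nrow(m)) {
    stop("groups must align with the samples of the count table", call. = FALSE)
  }
  keep <- !is.na(groups)
  m <- m[keep, , drop = FALSE]
  f <- factor(groups[keep])
  if (nlevels(f) < 1 || any(table(f) < 1)) stop("each group needs >= 1 replicate", call. = FALSE)
  set.seed(settings$seed)
  raw <- dmm_mcmc_cpp(m, as.integer(f) - 1L, nlevels(f),
                      settings$chains, settings$burn_in, settings$draws,
                      settings$prior_conc, settings$theta_scale,
                      settings$init_step, settings$target_accept)
  acc <- raw$accept_rate
  if (any(acc < 0.05 | acc > 0.95)) {
    warning(sprintf("%d of %d coordinate acceptance rates outside [0.05, 0.95]",
                    sum(acc < 0.05 | acc > 0.95), length(acc)))
  }
  structure(list(pi = raw$pi, theta = raw$theta, groups = levels(f),
                 taxa = colnames(m), n_samples = table(f),
                 accept_rate = acc, step = raw$step, settings = settings),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("Dirichlet-multinomial fit:", length(x$taxa), "taxa,",
      length(x$groups), "group(s) [", paste(x$groups, collapse = ", "), "]\n")
  cat(sprintf("  %d chains x %d draws (%d retained draws), burn-in %d\n",
              x$settings$chains, x$settings$draws,
              x$settings$chains * x$settings$draws, x$settings$burn_in))
  invisible(x)
}

# pooled draw matrix (chains*draws) x K for one group
pooled_pi <- function(fit, group) {
  g <- match(group, fit$groups)
  if (is.na(g)) stop("group not in fit: ", group, call. = FALSE)
  d <- dim(fit$pi)  # chains, draws, G, K
  matrix(fit$pi[, , g, ], nrow = d[1] * d[2], ncol = d[4],
         dimnames = list(NULL, fit$taxa))
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic potential scale reduction factor
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` computed per scalar parameter from
#' between- and within-chain variances.  For a `dmm_fit` the diagnostic is
#' computed on the unconstrained sampling scale (`log alpha = log(theta_g *
#' pi_gi)` for every group/taxon, plus `log theta_g`).
#'
#' @param x a `dmm_fit`, or a numeric array of draws with dimensions
#'   chains x draws (x parameters).
#' @param ... unused.
#' @return a tibble with `parameter` and `rhat`.  Parameters with zero
#'   within-chain variance get `NaN` with a warning.
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @rdname gelman_rubin
#' @export
gelman_rubin.default <- function(x, ...) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("need a chains x draws array", call. = FALSE)
  if (length(d) == 2) {
    x <- array(x, dim = c(d, 1))
    d <- dim(x)
  }
  if (d[1] < 2 || d[2] < 2) stop("need >= 2 chains with >= 2 draws", call. = FALSE)
  P <- prod(d[-(1:2)])
  x <- array(x, dim = c(d[1], d[2], P))
  rhat <- vapply(seq_len(P), function(p) rhat_scalar(x[, , p]), numeric(1))
  if (anyNA(rhat) || any(is.nan(rhat))) {
    warning("zero within-chain variance for ", sum(is.nan(rhat)),
            " parameter(s); Rhat reported as NaN")
  }
  tibble::tibble(parameter = paste0("param", seq_len(P)), rhat = rhat)
}

rhat_scalar <- function(draws) {
  # draws: chains x n
  n <- ncol(draws)
  means <- rowMeans(draws)
  W <- mean(apply(draws, 1, stats::var))
  if (!is.finite(W) || W == 0) return(NaN)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.dmm_fit <- function(x, ...) {
  d <- dim(x$pi)  # chains, draws, G, K
  out <- vector("list", d[3])
  for (g in seq_len(d[3])) {
    la <- log(x$pi[, , g, , drop = FALSE] *
                array(x$theta[, , g], dim = c(d[1], d[2], 1, d[4])))
    rh <- vapply(seq_len(d[4]), function(k) rhat_scalar(matrix(la[, , 1, k], d[1], d[2])),
                 numeric(1))
    rh_theta <- rhat_scalar(matrix(log(x$theta[, , g]), d[1], d[2]))
    out[[g]] <- tibble::tibble(
      parameter = c(paste0("log_alpha[", x$groups[g], ",", x$taxa, "]"),
                    paste0("log_theta[", x$groups[g], "]")),
      group = x$groups[g], rhat = c(rh, rh_theta))
  }
  res <- dplyr::bind_rows(out)
  if (any(is.nan(res$rhat))) {
    warning("zero within-chain variance for ", sum(is.nan(res$rhat)),
            " parameter(s); Rhat reported as NaN")
  }
  res
}

#' Posterior-difference comparison of two groups
#'
#' For each taxon, pools draws across chains and computes the posterior
#' distribution of the difference `pi_i,g1 - pi_i,g2`.  A taxon is flagged
#' as differentially abundant when at least `level` of that distribution's
#' mass lies strictly on one side of zero (i.e. `Pr(diff > 0) >= level` or
#' `<= 1 - level`; a probability exactly at the boundary counts as
#' flagged).  Posterior log10 fold changes `log10(pi_g1 / pi_g2)` are
#' summarised alongside.  No multiplicity correction is applied beyond this
#' credible-mass rule.
#'
#' @param fit a `dmm_fit` containing both groups.
#' @param g1,g2 group labels; positive differences/fold changes mean higher
#'   abundance in `g1`.
#' @param level credible level of the decision rule (default from the fit's
#'   settings, normally 0.95).
#' @return a `dmm_da` tibble: per-taxon posterior means per group, mean and
#'   equal-tailed interval of the difference, `pr_greater`, `flagged`,
#'   `direction`, and log10 fold-change summaries.
#' @export
compare_groups <- function(fit, g1, g2, level = fit$settings$level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  p1 <- pooled_pi(fit, g1)
  p2 <- pooled_pi(fit, g2)
  diff <- p1 - p2
  lfc <- log10(p1 / p2)
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  dq <- qs(diff)
  lq <- qs(lfc)
  pr <- colMeans(diff > 0)
  flagged <- pr >= level | pr <= 1 - level
  out <- tibble::tibble(
    taxon = fit$taxa,
    mean_g1 = unname(colMeans(p1)), mean_g2 = unname(colMeans(p2)),
    diff_mean = unname(colMeans(diff)),
    diff_lo = unname(dq[1, ]), diff_hi = unname(dq[2, ]),
    pr_greater = unname(pr), flagged = unname(flagged),
    direction = dplyr::case_when(!flagged ~ NA_character_,
                                 pr >= level ~ g1, TRUE ~ g2),
    log10_fc = unname(colMeans(lfc)),
    lfc_lo = unname(lq[1, ]), lfc_hi = unname(lq[2, ]),
    fold = unname(10^colMeans(lfc)))
  attr(out, "groups") <- c(g1, g2)
  attr(out, "level") <- level
  class(out) <- c("dmm_da", class(out))
  out
}

#' Posterior log10 fold changes between two groups
#'
#' @inheritParams compare_groups
#' @return tibble with per-taxon posterior mean and equal-tailed interval of
#'   `log10(pi_g1 / pi_g2)` plus the equivalent "x-fold" scale
#'   (`fold = 10^log10_fc`).
#' @export
log10_fold_changes <- function(fit, g1, g2, level = fit$settings$level) {
  res <- compare_groups(fit, g1, g2, level = level)
  tibble::as_tibble(res[, c("taxon", "log10_fc", "lfc_lo", "lfc_hi", "fold")])
}

#' The three standard two-group comparisons
#'
#' Fits three independent two-group Dirichlet-multinomial models with group
#' membership derived from the sample metadata — all diploid vs all
#' tetraploid hosts, Columbia vs Landsberg, and Col-4x vs the other three
#' planted groups pooled — and returns their posterior-difference results.
#' Soil controls are always excluded.
#'
#' @param ct a count table tibble.
#' @param meta a metadata tibble (see [read_metadata()]).
#' @param settings a [dmm_settings()]; each contrast's fit derives its seed
#'   from `settings$seed` so the three models are independent but jointly
#'   reproducible.
#' @param keep_fits retain the three `dmm_fit` objects (for diagnostics).
#' @return a named list of class `dmm_comparisons` with elements `ploidy`
#'   (2x vs 4x), `genotype` (Col vs Ler) and `col4x` (Col-4x vs others);
#'   each holds `result` (a `dmm_da` tibble) and optionally `fit`.
#' @export
standard_comparisons <- function(ct, meta, settings = dmm_settings(),
                                 keep_fits = TRUE) {
  meta <- meta[match(ct$sample_id, meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples", call. = FALSE)
  planted <- unique(meta$group[!meta$is_soil_control])
  needed <- c("Col-2x", "Col-4x", "Ler-2x", "Ler-4x")
  if (!all(needed %in% planted)) {
    stop("missing planted group(s): ", paste(setdiff(needed, planted), collapse = ", "),
         call. = FALSE)
  }
  spec <- list(ploidy = c("2x", "4x"), genotype = c("Col", "Ler"),
               col4x = c("Col-4x", "others"))
  out <- purrr::imap(spec, function(pair, ctr) {
    g <- contrast_groups(meta, ctr)
    s <- settings
    s$seed <- settings$seed + match(ctr, names(spec))
    fit <- fit_dmm(ct, g, s)
    res <- compare_groups(fit, pair[1], pair[2])
    if (keep_fits) list(result = res, fit = fit) else list(result = res)
  })
  structure(out, class = "dmm_comparisons")
}

#' @export
print.dmm_comparisons <- function(x, ...) {
  cat("Standard Dirichlet-multinomial comparisons:\n")
  for (nm in names(x)) {
    r <- x[[nm]]$result
    g <- attr(r, "groups")
    cat(sprintf("  %-9s %s vs %s: %d/%d taxa flagged\n", nm, g[1], g[2],
                sum(r$flagged), nrow(r)))
  }
  invisible(x)
}
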