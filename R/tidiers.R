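#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Dirichlet-multinomial fit
#'
#' One row per group x taxon: posterior mean and equal-tailed credible
#' interval of the group composition `pi`.
#'
#' @param x a `dmm_fit`.
#' @param conf.level credible level for the interval.
#' @param ... unused.
#' @return a tibble with `group`, `taxon`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.dmm_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  purrr::map_dfr(x$groups, function(g) {
    draws <- pooled_pi(x, g)
    qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    tibble::tibble(group = g, taxon = x$taxa, estimate = colMeans(draws),
                   conf.low = qs[1, ], conf.high = qs[2, ])
  })
}

#' Glance at a Dirichlet-multinomial fit
#'
#' @param x a `dmm_fit`.
#' @param ... unused.
#' @return a one-row tibble: chain geometry, total retained draws, taxa and
#'   group counts, posterior-mean intensity, worst R-hat and mean
#'   acceptance rate.
#' @export
glance.dmm_fit <- function(x, ...) {
  rh <- suppressWarnings(gelman_rubin(x))
  tibble::tibble(
    chains = x$settings$chains, draws_per_chain = x$settings$draws,
    total_draws = x$settings$chains * x$settings$draws,
    n_taxa = length(x$taxa), n_groups = length(x$groups),
    theta_mean = mean(x$theta),
    max_rhat = max(rh$rhat, na.rm = TRUE),
    mean_accept = mean(x$accept_rate))
}

#' Tidy a pairwise differential-abundance result
#'
#' @param x a `dmm_da` tibble from [compare_groups()].
#' @param ... unused.
#' @return the underlying tibble (already tidy).
#' @export
tidy.dmm_da <- function(x, ...) tibble::as_tibble(x)
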