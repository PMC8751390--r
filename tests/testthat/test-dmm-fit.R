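test_that("chain bookkeeping and determinism hold at the default geometry", {
  d <- small_two_group(K = 8, reps = 3, depth = c(500L, 900L))
  st <- dmm_settings(chains = 4, burn_in = 200, draws = 150, seed = 5)
  fit <- fit_dmm(d$counts, d$groups, st)
  expect_equal(dim(fit$pi), c(4, 150, 2, 8))
  expect_equal(dim(fit$theta), c(4, 150, 2))
  # compositions: every retained draw sums to one, intensities positive
  sums <- apply(fit$pi, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(fit$theta > 0))
  fit2 <- fit_dmm(d$counts, d$groups, st)
  expect_identical(fit$pi, fit2$pi)
  expect_identical(fit$theta, fit2$theta)
  # a different seed moves the draws
  st2 <- st; st2$seed <- 6L
  expect_false(identical(fit$pi, fit_dmm(d$counts, d$groups, st2)$pi))
})

test_that("defaults retain 4 x 1000 = 4000 draws", {
  st <- dmm_settings()
  expect_equal(st$chains * st$draws, 4000)
  expect_equal(st$burn_in, 1500)
})

test_that("two-group null data yields near-identical posterior means", {
  d <- small_two_group(K = 15, reps = 8, theta = 300, seed = 31,
                       depth = c(20000L, 40000L))
  fit <- fit_dmm(d$counts, d$groups, dmm_settings(burn_in = 800, draws = 600,
                                                  seed = 2))
  pA <- colMeans(rhizodmm:::pooled_pi(fit, "A"))
  pB <- colMeans(rhizodmm:::pooled_pi(fit, "B"))
  # null truth: differences only reflect replicate sampling noise
  se <- sqrt(d$truth$pi["A", ] * (1 - d$truth$pi["A", ]) *
               (1 / (d$spec$theta + 1)) * (1 / 8 + 1 / 8))
  expect_true(all(abs(pA - pB) < 3.5 * se + 0.002))
})

test_that("K = 2 single-group posterior matches the brute-force grid", {
  set.seed(77)
  n <- 5
  depths <- sample(150:400, n, replace = TRUE)
  x1 <- rbinom(n, depths, 0.3)
  counts <- cbind(t1 = x1, t2 = depths - x1)
  rownames(counts) <- paste0("s", 1:n)
  ct <- as_count_table(counts)
  fit <- fit_dmm(ct, rep("g", n), dmm_settings(seed = 3))
  draws <- rhizodmm:::pooled_pi(fit, "g")[, 1]
  oracle <- grid_posterior_k2(counts)
  expect_lt(abs(mean(draws) - oracle$mean), 0.005)
  expect_lt(ks_vs_grid(draws, oracle), 0.05)
})

test_that("posterior differences drive the credible decision rule", {
  # identical draw sets for both groups: nothing can be flagged
  set.seed(1)
  one <- array(runif(2 * 50 * 1 * 3, 0.1, 0.5), dim = c(2, 50, 1, 3))
  pi <- array(c(one, one), dim = c(2, 50, 2, 3))
  fit <- fake_dmm_fit(pi, groups = c("A", "B"))
  res <- compare_groups(fit, "A", "B")
  expect_false(any(res$flagged))
  expect_true(all(is.na(res$direction)))

  # constructed draws with Pr(diff > 0) = 0.96: flagged towards g1
  n <- 100
  diffs <- c(rep(0.01, 96), rep(-0.01, 4))
  base <- 0.3
  piA <- array(base + diffs / 2, dim = c(2, n / 2, 1, 1))
  piB <- array(base - diffs / 2, dim = c(2, n / 2, 1, 1))
  # make it a 2-taxon composition so rows sum to 1
  pi2 <- array(0, dim = c(2, n / 2, 2, 2))
  pi2[, , 1, 1] <- piA; pi2[, , 1, 2] <- 1 - piA
  pi2[, , 2, 1] <- piB; pi2[, , 2, 2] <- 1 - piB
  fit2 <- fake_dmm_fit(pi2, groups = c("A", "B"))
  res2 <- compare_groups(fit2, "A", "B")
  expect_equal(unname(res2$pr_greater[1]), 0.96)
  expect_true(res2$flagged[1])
  expect_equal(res2$direction[1], "A")
  # the boundary counts as flagged (>=)
  res95 <- compare_groups(fit2, "A", "B", level = 0.96)
  expect_true(res95$flagged[1])
  expect_error(compare_groups(fit2, "A", "B", level = 1.2), "level")
})

test_that("log10 fold changes follow from the composition draws", {
  pi <- array(0, dim = c(2, 10, 2, 2))
  pi[, , 1, 1] <- 0.08; pi[, , 1, 2] <- 0.92
  pi[, , 2, 1] <- 0.01; pi[, , 2, 2] <- 0.99
  fit <- fake_dmm_fit(pi, groups = c("hi", "lo"))
  lfc <- log10_fold_changes(fit, "hi", "lo")
  expect_equal(unname(lfc$log10_fc[1]), log10(8), tolerance = 1e-12)
  expect_equal(unname(lfc$fold[1]), 8, tolerance = 1e-12)
  same <- log10_fold_changes(fit, "hi", "hi")
  expect_true(all(same$log10_fc == 0))
})

test_that("a planted fold change is recovered inside its credible interval", {
  d <- small_two_group(K = 25, reps = 8, theta = 400, seed = 13,
                       depth = c(30000L, 60000L),
                       effects = data.frame(taxon = 4, group = "B", fold = 8))
  fit <- fit_dmm(d$counts, d$groups, dmm_settings(seed = 4))
  res <- compare_groups(fit, "B", "A")
  truth_lfc <- true_log10_fc(d$truth, "B", "A")$log10_fc[4]
  expect_true(res$flagged[4])
  expect_equal(res$direction[4], "B")
  expect_gt(truth_lfc, res$lfc_lo[4])
  expect_lt(truth_lfc, res$lfc_hi[4])
})

test_that("the three standard comparisons pool the design correctly", {
  spec <- synthetic_spec(n_taxa = 12, replicates = c("Col-2x" = 3, "Col-4x" = 3,
                                                     "Ler-2x" = 3, "Ler-4x" = 3),
                         n_soil = 2, theta = 200, depth_range = c(2000L, 4000L),
                         seed = 6)
  truth <- generate_truth(spec)
  sim <- simulate_counts(truth, spec)
  st <- dmm_settings(burn_in = 150, draws = 100, seed = 9)
  res <- standard_comparisons(sim$counts, sim$metadata, st)
  expect_named(res, c("ploidy", "genotype", "col4x"))
  expect_equal(unname(res$ploidy$fit$n_samples[c("2x", "4x")]), c(6, 6),
               ignore_attr = TRUE)
  expect_equal(unname(res$genotype$fit$n_samples[c("Col", "Ler")]), c(6, 6),
               ignore_attr = TRUE)
  expect_equal(unname(res$col4x$fit$n_samples[c("Col-4x", "others")]), c(3, 9),
               ignore_attr = TRUE)
  # soil controls never enter any fit
  for (nm in names(res)) {
    expect_equal(sum(res[[nm]]$fit$n_samples), 12)
  }
  # missing group errors
  bad <- dplyr::filter(sim$metadata, group != "Ler-4x")
  expect_error(standard_comparisons(sim$counts[sim$counts$sample_id %in%
                                                 bad$sample_id, ], bad, st),
               "Ler-4x")
})
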