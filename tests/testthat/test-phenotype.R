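test_that("zero-noise planted effects give exact sums of squares", {
  eff <- c("Col-4x" = -12, "Col-2x" = 4)
  tbl <- simulate_phenotypes(inoculum_effects = eff, noise_sd = 0,
                             n_per_cell = 2, seed = 1)
  # zero noise: the residual-variance warning is the degenerate-case contract
  suppressWarnings(a <- fit_anova3(tbl, "aboveground_biomass"))
  # balanced design: between-inoculum SS = n_per_level * sum((mean_l - grand)^2)
  lev_eff <- c("Col-2x" = 4, "Col-4x" = -12, "Ler-2x" = 0, "Ler-4x" = 0)
  n_per_level <- nrow(tbl) / 4
  want <- n_per_level * sum((lev_eff - mean(lev_eff))^2)
  expect_equal(a$sumsq[a$term == "inoculum"], want, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "genotype"], 0, tolerance = 1e-8)
  expect_equal(a$sumsq[a$term == "block"], 0, tolerance = 1e-8)
  # df: terms + residual sum to n - 1
  expect_equal(sum(a$df), nrow(tbl) - 1)
})

test_that("constant responses yield zero SS and NaN F with a warning", {
  tbl <- simulate_phenotypes(noise_sd = 0, seed = 1)
  expect_warning(a <- fit_anova3(tbl, "aboveground_biomass"), "NaN")
  expect_true(all(a$sumsq[a$term != "Residuals"] < 1e-20))
  expect_true(all(is.nan(a$statistic[a$term != "Residuals"])))
})

test_that("the ANOVA table is invariant to row order and balanced-design term order", {
  tbl <- simulate_phenotypes(inoculum_effects = c("Ler-2x" = 6),
                             genotype_effects = c("Col-4x" = -3),
                             noise_sd = 2, seed = 4)
  a1 <- fit_anova3(tbl, "aboveground_biomass")
  set.seed(1)
  a2 <- fit_anova3(tbl[sample(nrow(tbl)), ], "aboveground_biomass")
  expect_equal(a1$sumsq, a2$sumsq, tolerance = 1e-10)
  # balanced data: sequential SS equal marginal SS (drop-one comparison)
  df <- as.data.frame(tbl)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  full <- lm(aboveground_biomass ~ inoculum + genotype + block, df)
  drop1_ss <- drop1(full, test = "F")
  for (term in c("inoculum", "genotype", "block")) {
    expect_equal(a1$sumsq[a1$term == term],
                 drop1_ss[term, "Sum of Sq"], tolerance = 1e-8)
  }
})

test_that("residualisation removes nuisance factors and centres the data", {
  tbl <- simulate_phenotypes(inoculum_effects = c("Col-4x" = -10),
                             noise_sd = 0.5, n_per_cell = 3, seed = 6)
  r <- residualize(tbl, "aboveground_biomass")
  expect_equal(sum(r$.resid), 0, tolerance = 1e-9)
  rs <- residual_summary(tbl, "aboveground_biomass")
  worst <- rs$inoculum[which.min(rs$mean_resid)]
  expect_equal(worst, "Col-4x")
  gap <- mean(rs$mean_resid[rs$inoculum != "Col-4x"]) -
    rs$mean_resid[rs$inoculum == "Col-4x"]
  expect_lt(abs(gap - 10), 4 * 0.5 / sqrt(min(rs$n)))
  # zero effects anywhere: residuals are just the centred response
  t0 <- simulate_phenotypes(noise_sd = 1, seed = 9)
  r0 <- residualize(t0, "aboveground_biomass")
  expect_equal(r0$.resid,
               r0$aboveground_biomass - mean(r0$aboveground_biomass),
               tolerance = 0.5)
})

test_that("Tukey HSD matches the studentized-range closed form", {
  # one balanced factor, no genotype/block structure beyond single levels is
  # not allowed, so use a design with inert genotype/block and read the
  # inoculum comparisons
  tbl <- simulate_phenotypes(inoculum_effects = c("Col-4x" = -8, "Ler-2x" = 3),
                             noise_sd = 2, n_per_cell = 3, seed = 12)
  tk <- tukey_hsd(tbl, "aboveground_biomass", "inoculum")
  a <- fit_anova3(tbl, "aboveground_biomass")
  mse <- a$meansq[a$term == "Residuals"]
  dfe <- a$df[a$term == "Residuals"]
  n_per <- nrow(tbl) / 4
  for (i in seq_len(nrow(tk$comparisons))) {
    want <- tukey_oracle_p(tk$comparisons$estimate[i], mse, n_per, 4, dfe)
    expect_equal(tk$comparisons$adj.p.value[i], want, tolerance = 1e-6)
  }
  # Tukey-adjusted p never undercuts the unadjusted pairwise p
  for (i in seq_len(nrow(tk$comparisons))) {
    pc <- planned_contrast(tbl, "aboveground_biomass",
                           c(tk$comparisons$level1[i], tk$comparisons$level2[i]))
    expect_gte(tk$comparisons$adj.p.value[i], pc$p.value - 1e-10)
  }
})

test_that("letter displays separate and merge as the p values dictate", {
  hot <- simulate_phenotypes(inoculum_effects = c("Col-4x" = -30),
                             noise_sd = 0.05, n_per_cell = 2, seed = 3)
  tk <- tukey_hsd(hot, "aboveground_biomass", "inoculum")
  lets <- tk$letters
  solo <- lets$letters[lets$level == "Col-4x"]
  others <- unique(lets$letters[lets$level != "Col-4x"])
  expect_equal(nchar(solo), 1)
  expect_length(others, 1)
  expect_false(solo == others)
  # direct letter-algebra checks on prescribed p-value patterns
  lev <- c("w", "x", "y", "z")
  pairs <- t(combn(lev, 2))
  mk <- function(p) tibble::tibble(contrast = paste(pairs[, 2], pairs[, 1],
                                                    sep = "-"),
                                   level1 = pairs[, 2], level2 = pairs[, 1],
                                   adj.p.value = p)
  all_ns <- rhizodmm:::compact_letters(lev, mk(rep(0.9, 6)))
  expect_true(all(all_ns$letters == "a"))
  all_sig <- rhizodmm:::compact_letters(lev, mk(rep(0.001, 6)))
  expect_equal(sort(all_sig$letters), letters[1:4])
  # chain overlap: w~x, x~y, y~z non-significant; w-y, w-z, x-z significant
  p <- c(0.5, 0.01, 0.01, 0.5, 0.01, 0.5)
  names(p) <- paste(pairs[, 2], pairs[, 1], sep = "-")
  chain <- rhizodmm:::compact_letters(lev, mk(unname(p[paste(pairs[, 2],
                                                             pairs[, 1],
                                                             sep = "-")])))
  # expects three overlapping groups {w,x}, {x,y}, {y,z}
  expect_equal(nchar(chain$letters), c(1, 2, 2, 1))
})

test_that("planned contrasts are antisymmetric and well calibrated", {
  tbl <- simulate_phenotypes(inoculum_effects = c("Col-4x" = -5),
                             noise_sd = 3, n_per_cell = 2, seed = 21)
  c1 <- planned_contrast(tbl, "aboveground_biomass", c("Col-2x", "Col-4x"))
  c2 <- planned_contrast(tbl, "aboveground_biomass", c("Col-4x", "Col-2x"))
  expect_equal(c1$estimate, -c2$estimate)
  expect_equal(c1$p.value, c2$p.value)
  flat <- simulate_phenotypes(noise_sd = 1e-12, seed = 2)
  c0 <- planned_contrast(flat, "aboveground_biomass", c("Ler-2x", "Ler-4x"))
  expect_lt(abs(c0$estimate), 1e-10)
})

test_that("contrast power tracks the noncentral-t closed form", {
  delta <- 1.5; sigma <- 3; n_cell <- 2; blocks <- 4
  n_per_level <- n_cell * blocks * 4   # per inoculum level
  reps <- 400
  hits <- 0
  for (i in seq_len(reps)) {
    tbl <- simulate_phenotypes(inoculum_effects = c("Col-4x" = -delta),
                               noise_sd = sigma, n_per_cell = n_cell,
                               seed = 1000 + i)
    p <- planned_contrast(tbl, "aboveground_biomass",
                          c("Col-2x", "Col-4x"))$p.value
    hits <- hits + (p < 0.05)
  }
  se_diff <- sigma * sqrt(2 / n_per_level)
  dfe <- 4 * 4 * blocks * n_cell - 1 - 3 * 3
  ncp <- delta / se_diff
  crit <- qt(0.975, dfe)
  power <- 1 - pt(crit, dfe, ncp) + pt(-crit, dfe, ncp)
  expect_lt(abs(hits / reps - power), 3 * sqrt(power * (1 - power) / reps) + 0.02)
})
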