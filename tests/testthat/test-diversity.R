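test_that("dissimilarities reproduce their closed forms", {
  m <- rbind(a = c(6, 0, 2), b = c(2, 2, 2), c = c(6, 0, 2))
  colnames(m) <- paste0("t", 1:3)
  ct <- as_count_table(m)
  bc <- as.matrix(bray_curtis(ct))
  expect_equal(bc["a", "b"], 6 / 14)
  expect_equal(bc["a", "c"], 0)
  disj <- as_count_table(rbind(x = c(5, 0), y = c(0, 3)) |>
                           (\(z) {colnames(z) <- c("t1", "t2"); z})())
  expect_equal(as.matrix(bray_curtis(disj))["x", "y"], 1)
  expect_equal(as.matrix(jaccard(disj))["x", "y"], 1)

  pj <- rbind(u = c(1, 1, 1, 0), v = c(0, 5, 2, 9))
  colnames(pj) <- paste0("t", 1:4)
  jm <- as.matrix(jaccard(as_count_table(pj)))
  expect_equal(jm["u", "v"], 0.5)  # sets {1,2,3} vs {2,3,4}
  expect_equal(diag(jm), c(u = 0, v = 0))
})

test_that("binary Bray-Curtis and Jaccard obey the 2B/(1+B) identity", {
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rbinom(60, 1, 0.5), 6, 10)
    m[rowSums(m) == 0, 1] <- 1
    dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:10))
    ct <- as_count_table(m)
    B <- as.matrix(bray_curtis(ct))   # counts already binary
    J <- as.matrix(jaccard(ct))
    expect_equal(J, 2 * B / (1 + B), tolerance = 1e-12)
  }
})

test_that("PERMANOVA matches adonis2 and full enumeration on n = 6", {
  set.seed(3)
  m <- matrix(rpois(6 * 8, 20), 6, 8,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  ct <- as_count_table(m)
  d <- bray_curtis(ct)
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g)
  expect_equal(res$method, "enumeration")
  expect_equal(res$n_permutations, 20)

  # observed statistic against the independent vegan implementation
  ad <- vegan::adonis2(d ~ grp, data = data.frame(grp = g), permutations = 99)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)

  # enumeration p against brute force with adonis2 recomputing F per labeling
  labs <- combn(6, 3)
  F_all <- apply(labs, 2, function(idx) {
    gg <- rep("B", 6); gg[idx] <- "A"
    vegan::adonis2(d ~ grp, data = data.frame(grp = gg), permutations = 0)$F[1]
  })
  expect_equal(res$p.value, mean(F_all >= res$statistic - 1e-12))
})

test_that("sampled permutation p converges to the enumeration value", {
  set.seed(8)
  m <- matrix(rpois(8 * 10, 1.2), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  m[, 1] <- m[, 1] + 1  # keep depths positive
  ct <- as_count_table(m)
  d <- jaccard(ct)
  g <- rep(c("A", "B"), each = 4)
  exact <- permanova(d, g)               # 70 assignments, enumerated
  sampled <- permanova(d, g, n_perm = 9999, seed = 1, exact_limit = 1)
  expect_equal(sampled$method, "sampled")
  expect_lt(abs(sampled$p.value - exact$p.value), 2 / sqrt(9999))
})

test_that("separated clusters give R2 near one at the enumeration floor", {
  m <- rbind(matrix(rep(c(100, 0, 0, 2), each = 3), 3) + rpois(12, 1),
             matrix(rep(c(0, 100, 3, 0), each = 3), 3) + rpois(12, 1))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:4))
  res <- permanova(bray_curtis(as_count_table(m)), rep(c("A", "B"), each = 3))
  expect_gt(res$R2, 0.9)
  expect_equal(res$p.value, 2 / 20)  # observed labeling and its mirror
  expect_error(permanova(bray_curtis(as_count_table(m)), paste0("g", 1:6)),
               "residual")
  expect_warning(permanova(bray_curtis(as_count_table(m)),
                           c("A", "A", "A", "A", "A", "B")),
                 "< 2 members")
})

test_that("PCoA recovers planted Euclidean configurations", {
  set.seed(5)
  pts <- cbind(runif(7, -3, 3), runif(7, -3, 3))
  rownames(pts) <- paste0("s", 1:7)
  d <- dist(pts)
  res <- pcoa(d)
  expect_equal(ncol(res$coordinates) - 1, 2)
  rec <- as.matrix(res$coordinates[, -1])
  pr <- vegan::procrustes(pts, rec, symmetric = FALSE)
  expect_lt(max(abs(pr$Yrot + matrix(pr$translation, 7, 2, byrow = TRUE) - pts)),
            1e-8)
  # all-equal distances among 3 points: two equal positive eigenvalues
  d3 <- as.dist(matrix(1, 3, 3) - diag(3))
  e <- pcoa(d3)$eigenvalues
  pos <- e[e > 1e-12]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # duplicated sample collapses to the same coordinates
  ptsd <- rbind(pts, s8 = pts[1, ])
  resd <- pcoa(dist(ptsd))
  cd <- as.matrix(resd$coordinates[, -1])
  expect_lt(max(abs(cd[1, ] - cd[8, ])), 1e-8)
})

test_that("negative eigenvalues are reported, not corrected", {
  set.seed(9)
  m <- matrix(rpois(12 * 20, 10), 12, 20,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:20)))
  e <- pcoa(bray_curtis(as_count_table(m)))$eigenvalues
  expect_true(any(e < 0))
})

test_that("Shannon diversity matches closed forms", {
  m <- rbind(unif = rep(3, 10), single = c(7, rep(0, 9)),
             mix = c(10, 5, 5, rep(0, 7)))
  colnames(m) <- paste0("t", 1:10)
  h <- shannon(as_count_table(m))
  expect_equal(h$shannon[1], log(10), tolerance = 1e-12)
  expect_equal(h$shannon[2], 0)
  expect_equal(h$shannon[3], -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))),
               tolerance = 1e-12)
  # invariant to zero-count taxa
  h2 <- shannon(as_count_table(m[, 1:3][3, , drop = FALSE] |>
                                 (\(z) {rownames(z) <- "mix"; z})()))
  expect_equal(h$shannon[3], h2$shannon[1])
})

test_that("Welch test matches the textbook formulas", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  got <- welch_t(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$parameter, want$df, tolerance = 1e-10)
  expect_equal(got$p.value, want$p, tolerance = 1e-10)
  # same values: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # equal n and variance: equals the pooled-variance statistic
  set.seed(2)
  a <- rnorm(6); b <- a + 0.8
  expect_equal(welch_t(a, b)$statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic))
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("the study-style PERMANOVA table subsets before computing distances", {
  spec <- synthetic_spec(n_taxa = 15, replicates = c("Col-2x" = 3, "Col-4x" = 3,
                                                     "Ler-2x" = 3, "Ler-4x" = 3),
                         n_soil = 3, theta = 100, depth_range = c(1000L, 2000L),
                         seed = 14)
  sim <- simulate_counts(generate_truth(spec), spec)
  tab <- permanova_table(sim$counts, sim$metadata, n_perm = 99, seed = 2)
  expect_setequal(unique(tab$metric), c("jaccard", "bray_curtis"))
  expect_equal(tab$n[tab$comparison == "plant vs soil"], c(15, 15))
  expect_equal(tab$n[tab$comparison == "Col-2x vs Col-4x"], c(6, 6))
  expect_equal(tab$n[tab$comparison == "Landsberg vs Columbia"], c(12, 12))
  expect_true(all(tab$p.value > 0 & tab$p.value <= 1))
  expect_true(all(tab$R2 >= 0 & tab$R2 <= 1))
})
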