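#' Community dissimilarities
#'
#' `bray_curtis()` computes the abundance-based Bray-Curtis dissimilarity on
#' raw counts, `BC(u, v) = sum|u_i - v_i| / sum(u_i + v_i)` (the adonis
#' convention; no rarefaction or normalisation is applied first).
#' `jaccard()` binarises the counts and computes the presence-absence set
#' dissimilarity `J = 1 - |intersection| / |union|`; set
#' `quantitative = TRUE` for the abundance-weighted Jaccard variant.
#'
#' @param ct a count table tibble.
#' @param quantitative for `jaccard()`: use the quantitative
#'   (abundance-based) variant instead of presence-absence.
#' @return a `dist` object with a `"metric"` attribute.
#' @examples
#' ct <- as_count_table(matrix(c(6, 2, 0, 2, 2, 2), 2, 3,
#'   dimnames = list(c("a", "b"), c("t1", "t2", "t3"))))
#' bray_curtis(ct)  # 6/14
#' @export
bray_curtis <- function(ct) {
  validate_count_table(ct, require_positive_depth = TRUE)
  d <- vegan::vegdist(count_matrix(ct), method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' @rdname bray_curtis
#' @export
jaccard <- function(ct, quantitative = FALSE) {
  validate_count_table(ct, require_positive_depth = TRUE)
  d <- vegan::vegdist(count_matrix(ct), method = "jaccard",
                      binary = !quantitative)
  attr(d, "metric") <- if (quantitative) "jaccard_quantitative" else "jaccard"
  d
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance from a distance matrix
#' (the adonis approach): the total sum of squares is partitioned via the
#' Gower-centred inner-product decomposition,
#' `SS_total = sum(d_ij^2)/n`, `SS_within = sum_g sum(d_ij^2 within g)/n_g`,
#' and the pseudo-F statistic is
#' `F = (SS_between/(k-1)) / (SS_within/(n-k))`.  Significance comes from
#' permuting group labels: `p = (1 + #permuted F >= observed) / (1 +
#' n_perm)`.  When the number of distinct label assignments is at most
#' `exact_limit`, all of them are enumerated instead and `p` is the exact
#' permutation tail probability.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param grouping group label per sample (length n, >= 2 groups).
#' @param n_perm number of random permutations when enumeration is not used.
#' @param seed optional integer seed for the permutation sampler.
#' @param exact_limit enumerate exhaustively when the number of distinct
#'   assignments does not exceed this.
#' @param keep_permutations return the permuted F sample as an attribute.
#' @return a one-row tibble of class `permanova_result`: `statistic`
#'   (pseudo-F), `R2`, `p.value`, `df_between`, `df_within`,
#'   `n_permutations`, `method` (`"enumeration"` or `"sampled"`).
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = NULL,
                      exact_limit = 10000, keep_permutations = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == n)
  f <- factor(grouping)
  k <- nlevels(f)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (k == n) stop("every sample its own group: no residual df", call. = FALSE)
  if (any(table(f) < 2)) warning("group(s) with < 2 members")
  D2 <- D^2
  SS_T <- sum(D2) / (2 * n)
  if (SS_T <= 0) stop("all dissimilarities are zero; nothing to partition", call. = FALSE)
  gi <- as.integer(f)
  # pseudo-F for each column of a label matrix at once:
  # SS_within = sum_g (1' D2[g,g] 1) / (2 n_g), via indicator matrices
  f_stat_batch <- function(L) {
    SS_W <- 0
    for (lev in seq_len(k)) {
      X <- (L == lev) * 1
      SS_W <- SS_W + colSums((D2 %*% X) * X) / (2 * colSums(X))
    }
    ((SS_T - SS_W) / (k - 1)) / (SS_W / (n - k))
  }
  F_obs <- f_stat_batch(matrix(gi, n, 1))
  sizes <- table(f)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_assign <= exact_limit) {
    labs <- enumerate_assignments(as.integer(sizes))
    F_perm <- f_stat_batch(labs)
    p <- mean(F_perm >= F_obs - 1e-12)
    method <- "enumeration"
    n_used <- ncol(labs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(i) sample(gi), integer(n))
    F_perm <- f_stat_batch(perms)
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
    method <- "sampled"
    n_used <- n_perm
  }
  out <- tibble::tibble(statistic = F_obs,
                        R2 = F_obs * (k - 1) / (F_obs * (k - 1) + (n - k)),
                        p.value = p, df_between = k - 1, df_within = n - k,
                        n_permutations = n_used, method = method)
  if (keep_permutations) attr(out, "permuted_F") <- F_perm
  class(out) <- c("permanova_result", class(out))
  out
}

# all distinct assignments of groups with the given sizes, as an
# n x n_assignments integer matrix of group indices
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining_idx, g, current) {
    if (g == length(sizes)) {
      lab <- integer(n)
      for (i in seq_along(current)) lab[current[[i]]] <- i
      lab[remaining_idx] <- g
      out[[length(out) + 1]] <<- lab
      return(invisible())
    }
    cmb <- utils::combn(remaining_idx, sizes[g], simplify = FALSE)
    for (sel in cmb) {
      recurse(setdiff(remaining_idx, sel), g + 1, c(current, list(sel)))
    }
  }
  recurse(seq_len(n), 1L, list())
  do.call(cbind, out)
}

#' PERMANOVA table for the standard study comparisons
#'
#' Runs one-factor PERMANOVAs on Jaccard and Bray-Curtis dissimilarities
#' for the standard comparisons of a genotype-x-ploidy rhizosphere design:
#' plant vs unplanted soil, Landsberg vs Columbia, diploid vs tetraploid,
#' the two within-genotype ploidy contrasts, and Col-4x vs all other
#' planted groups.  For every comparison the distance matrix is computed
#' *after* subsetting to the samples involved; soil controls enter only the
#' plant-vs-soil row.
#'
#' @param ct a count table tibble.
#' @param meta a metadata tibble.
#' @param n_perm,seed,exact_limit passed to [permanova()]; each row uses an
#'   independent seed derived from `seed`.
#' @return a tibble with `comparison`, `metric`, `p.value`, `statistic`
#'   (pseudo-F), `R2`, `n`, `method`.
#' @export
permanova_table <- function(ct, meta, n_perm = 999, seed = 1L,
                            exact_limit = 10000) {
  meta <- meta[match(ct$sample_id, meta$sample_id), ]
  comps <- list(
    "plant vs soil" = list(keep = rep(TRUE, nrow(meta)),
                           g = ifelse(meta$is_soil_control, "soil", "plant")),
    "Landsberg vs Columbia" = list(keep = !meta$is_soil_control,
                                   g = meta$genotype),
    "diploid vs tetraploid" = list(keep = !meta$is_soil_control,
                                   g = meta$ploidy),
    "Col-2x vs Col-4x" = list(keep = meta$group %in% c("Col-2x", "Col-4x"),
                              g = meta$group),
    "Ler-2x vs Ler-4x" = list(keep = meta$group %in% c("Ler-2x", "Ler-4x"),
                              g = meta$group),
    "Col-4x vs all others" = list(keep = !meta$is_soil_control,
                                  g = contrast_groups(meta, "col4x")))
  rows <- list()
  i <- 0L
  for (nm in names(comps)) {
    keep <- comps[[nm]]$keep & !is.na(comps[[nm]]$g)
    if (length(unique(comps[[nm]]$g[keep])) < 2) next  # e.g. no soil controls
    sub <- ct[keep, , drop = FALSE]
    for (metric in c("jaccard", "bray_curtis")) {
      i <- i + 1L
      dd <- if (metric == "jaccard") jaccard(sub) else bray_curtis(sub)
      r <- permanova(dd, comps[[nm]]$g[keep], n_perm = n_perm,
                     seed = seed + i, exact_limit = exact_limit)
      rows[[i]] <- tibble::tibble(comparison = nm, metric = metric,
                                  p.value = r$p.value, statistic = r$statistic,
                                  R2 = r$R2, n = sum(keep), method = r$method)
    }
  }
  dplyr::bind_rows(rows)
}

#' Principal-coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower-centred
#' squared-distance matrix.  Coordinates are ordered by eigenvalue; all
#' eigenvalues, including negative ones (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis), are reported uncorrected.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param k number of coordinate axes to return (default: all positive).
#' @return a `pcoa_result` list: `coordinates` (tibble with `sample_id` and
#'   `Axis1..Axisk`), `eigenvalues`, and `rel_eig` (share of the positive
#'   eigenvalue total).
#' @export
pcoa <- function(d, k = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  # cmdscale warns when fewer than k eigenvalues are positive; that is the
  # expected situation for non-Euclidean dissimilarities and is reported
  # through the eigenvalue vector instead
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > 1e-8 * max(abs(eig)))
  k <- min(k %||% npos, max(npos, 1))
  coords <- fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = tibble::add_column(
      tibble::as_tibble(coords),
      sample_id = rownames(D) %||% as.character(seq_len(n)), .before = 1),
    eigenvalues = eig,
    rel_eig = pmax(eig, 0) / sum(pmax(eig, 0))),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates) - 1,
      "axes retained\n")
  cat("  first axes explain",
      paste0(round(100 * utils::head(x$rel_eig, 3), 1), "%", collapse = ", "),
      "of positive-eigenvalue variation\n")
  if (any(x$eigenvalues < 0)) {
    cat("  note:", sum(x$eigenvalues < 0), "negative eigenvalue(s) present\n")
  }
  invisible(x)
}

#' Shannon diversity
#'
#' Per-sample Shannon index `H = -sum p_i log p_i` (natural log) over the
#' sample's nonzero relative abundances.
#'
#' @param ct a count table tibble.
#' @return tibble with `sample_id` and `shannon`.
#' @export
shannon <- function(ct) {
  validate_count_table(ct, require_positive_depth = TRUE)
  tibble::tibble(sample_id = ct$sample_id,
                 shannon = unname(vegan::diversity(count_matrix(ct),
                                                   index = "shannon")))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return one-row tibble: `estimate` (mean of `x` minus mean of `y`),
#'   `statistic`, `parameter` (df), `p.value`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
                 statistic = unname(tt$statistic),
                 parameter = unname(tt$parameter),
                 p.value = tt$p.value)
}

#' Shannon diversity contrasts across the study groups
#'
#' Computes per-sample Shannon diversity on planted samples and runs the
#' standard Welch two-sample tests: genotype (Col vs Ler), ploidy (2x vs
#' 4x), and ploidy nested within each genotype.  Also reports the grand
#' mean and its standard error.
#'
#' @param ct a count table tibble.
#' @param meta a metadata tibble.
#' @return list with `per_sample` (tibble), `tests` (tibble of the four
#'   Welch tests), `mean`, `se`, `n`.
#' @export
shannon_summary <- function(ct, meta) {
  meta <- meta[match(ct$sample_id, meta$sample_id), ]
  keep <- !meta$is_soil_control
  div <- shannon(ct[keep, , drop = FALSE])
  div$genotype <- meta$genotype[keep]
  div$ploidy <- meta$ploidy[keep]
  h <- div$shannon
  tests <- dplyr::bind_rows(
    dplyr::mutate(welch_t(h[div$genotype == "Col"], h[div$genotype == "Ler"]),
                  test = "genotype (Col vs Ler)"),
    dplyr::mutate(welch_t(h[div$ploidy == "2x"], h[div$ploidy == "4x"]),
                  test = "ploidy (2x vs 4x)"),
    dplyr::mutate(welch_t(h[div$genotype == "Ler" & div$ploidy == "2x"],
                          h[div$genotype == "Ler" & div$ploidy == "4x"]),
                  test = "ploidy within Ler"),
    dplyr::mutate(welch_t(h[div$genotype == "Col" & div$ploidy == "2x"],
                          h[div$genotype == "Col" & div$ploidy == "4x"]),
                  test = "ploidy within Col"))
  list(per_sample = div, tests = tests[, c("test", names(tests)[1:4])],
       mean = mean(h), se = stats::sd(h) / sqrt(length(h)), n = length(h))
}
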