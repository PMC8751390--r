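#' Read a phenotype table
#'
#' Imports the plant-performance table for the microbiome-feedback
#' experiment: columns `plant_id`, `genotype`, `inoculum`, `block`, and one
#' or more numeric responses (e.g. `aboveground_biomass`,
#' `belowground_biomass`, phenology, seed mass).  Missing responses are
#' allowed and dropped listwise per analysis.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  names(df)[1] <- "plant_id"
  for (col in c("genotype", "inoculum", "block")) {
    if (!col %in% names(df)) stop("phenotype table lacks column ", col, call. = FALSE)
    df[[col]] <- as.character(df[[col]])
  }
  tibble::as_tibble(df)
}

pheno_model_frame <- function(tbl, response, factors) {
  stopifnot(response %in% names(tbl))
  keep <- stats::complete.cases(tbl[, c(factors, response)])
  df <- as.data.frame(tbl[keep, c(factors, response)])
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2) stop("factor ", f, " has < 2 levels", call. = FALSE)
  }
  names(df)[names(df) == response] <- ".y"
  df
}

#' Fixed-effect three-way ANOVA
#'
#' Fits the main-effects linear model `response ~ inoculum + genotype +
#' block` by least squares (all factors fixed) and returns the sequential
#' (type I) ANOVA table in that term order — on a balanced design the
#' sequential and marginal sums of squares coincide.  The genotype x
#' inoculum interaction can be added behind a flag but is off by default.
#'
#' @param tbl a phenotype tibble.
#' @param response name of the response column.
#' @param include_interaction add `genotype:inoculum`.
#' @return a tibble of class `anova3_result` with `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value` (including the residual row); the
#'   fitted `lm` is attached as attribute `"model"`.
#' @export
fit_anova3 <- function(tbl, response, include_interaction = FALSE) {
  df <- pheno_model_frame(tbl, response, c("inoculum", "genotype", "block"))
  form <- if (include_interaction) {
    .y ~ inoculum + genotype + block + genotype:inoculum
  } else {
    .y ~ inoculum + genotype + block
  }
  m <- stats::lm(form, data = df)
  if (anyNA(stats::coef(m))) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(names(stats::coef(m))[is.na(stats::coef(m))], collapse = ", "),
         call. = FALSE)
  }
  a <- withCallingHandlers(
    stats::anova(m),
    warning = function(w) {
      # the zero-residual case is detected and reported explicitly below
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (a["Residuals", "Mean Sq"] <= .Machine$double.eps * mean(df$.y^2 + 1)) {
    warning("residual variance is zero; F statistics reported as NaN")
    a$`F value` <- c(rep(NaN, nrow(a) - 1), NA)
    a$`Pr(>F)` <- c(rep(NaN, nrow(a) - 1), NA)
  }
  out <- tibble::tibble(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                        meansq = a$`Mean Sq`, statistic = a$`F value`,
                        p.value = a$`Pr(>F)`)
  attr(out, "model") <- m
  attr(out, "response") <- response
  class(out) <- c("anova3_result", class(out))
  out
}

#' Residualise a response for display
#'
#' Returns least-squares residuals after removing nuisance factors
#' (genotype and block by default), the convention for displaying inoculum
#' effects on plant performance: group means of these residuals by inoculum
#' are the bar heights of a residual-biomass figure.
#'
#' @param tbl a phenotype tibble.
#' @param response name of the response column.
#' @param remove factors to regress out.
#' @return `tbl` rows used in the fit with an added `.resid` column.
#' @export
residualize <- function(tbl, response, remove = c("genotype", "block")) {
  df <- pheno_model_frame(tbl, response, remove)
  m <- stats::lm(stats::reformulate(remove, ".y"), data = df)
  keep <- stats::complete.cases(tbl[, c(remove, response)])
  out <- tbl[keep, , drop = FALSE]
  out$.resid <- unname(stats::residuals(m))
  out
}

#' Residual means by inoculum
#'
#' @param tbl a phenotype tibble.
#' @param response name of the response column.
#' @param remove nuisance factors passed to [residualize()].
#' @return tibble with `inoculum`, `mean_resid`, `se`, `n`.
#' @export
residual_summary <- function(tbl, response, remove = c("genotype", "block")) {
  r <- residualize(tbl, response, remove)
  dplyr::summarise(dplyr::group_by(r, .data$inoculum),
                   mean_resid = mean(.data$.resid),
                   se = stats::sd(.data$.resid) / sqrt(dplyr::n()),
                   n = dplyr::n(), .groups = "drop")
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise comparisons of the levels of `factor` using the studentized
#' range, with the residual mean square of the full three-way model
#' (`response ~ inoculum + genotype + block`) as the error term, plus a
#' compact letter display (levels sharing a letter do not differ at
#' `alpha`).
#'
#' @param tbl a phenotype tibble.
#' @param response name of the response column.
#' @param factor factor whose levels are compared (default `"inoculum"`).
#' @param alpha family-wise error rate for the letter display.
#' @param include_interaction passed to the underlying ANOVA model.
#' @return a list of class `tukey_result`: `comparisons` (tibble with
#'   `contrast`, `estimate`, `conf.low`, `conf.high`, `adj.p.value`) and
#'   `letters` (tibble with `level`, `letters`).
#' @export
tukey_hsd <- function(tbl, response, factor = "inoculum", alpha = 0.05,
                      include_interaction = FALSE) {
  df <- pheno_model_frame(tbl, response, c("inoculum", "genotype", "block"))
  if (any(table(df[[factor]]) < 2)) {
    stop("every level of ", factor, " needs >= 2 observations", call. = FALSE)
  }
  form <- if (include_interaction) {
    .y ~ inoculum + genotype + block + genotype:inoculum
  } else {
    .y ~ inoculum + genotype + block
  }
  fit <- stats::aov(form, data = df)
  tk <- stats::TukeyHSD(fit, which = factor)[[factor]]
  lev <- levels(df[[factor]])
  # recover the level pair for each row without parsing names (levels may
  # themselves contain the separator, e.g. "Col-4x")
  cmb <- utils::combn(lev, 2)
  expected <- paste(cmb[2, ], cmb[1, ], sep = "-")
  idx <- match(rownames(tk), expected)
  if (anyNA(idx)) stop("unexpected Tukey contrast labels", call. = FALSE)
  comp <- tibble::tibble(contrast = rownames(tk),
                         level1 = cmb[2, idx], level2 = cmb[1, idx],
                         estimate = tk[, "diff"],
                         conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
                         adj.p.value = tk[, "p adj"])
  structure(list(comparisons = comp,
                 letters = compact_letters(lev, comp, alpha),
                 factor = factor, response = response, alpha = alpha),
            class = "tukey_result")
}

# compact letter display (insert-and-absorb): start from one group holding
# every level; each significant pair splits the groups containing both;
# redundant subset groups are absorbed; letters are assigned per group
compact_letters <- function(levels, comparisons, alpha = 0.05) {
  k <- length(levels)
  groups <- list(seq_len(k))
  for (i in seq_len(nrow(comparisons))) {
    if (comparisons$adj.p.value[i] >= alpha) next
    a <- match(comparisons$level1[i], levels)
    b <- match(comparisons$level2[i], levels)
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    new_groups <- unique(lapply(new_groups, sort))
    is_proper_subset <- function(x) {
      any(vapply(new_groups, function(y) {
        length(x) < length(y) && all(x %in% y)
      }, logical(1)))
    }
    groups <- new_groups[!vapply(new_groups, is_proper_subset, logical(1))]
  }
  lab <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(groups, function(g) i %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  tibble::tibble(level = levels, letters = lab)
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD on %s for %s (alpha = %g)\n", x$factor, x$response,
              x$alpha))
  print(x$comparisons, n = Inf)
  cat("letter display:\n")
  print(x$letters, n = Inf)
  invisible(x)
}

#' Planned single-degree-of-freedom contrast
#'
#' Contrasts two levels of `factor` (default inoculum) using the level
#' means and residual variance of the full main-effects model.  The p
#' value is unadjusted: the comparison is planned, not post hoc.
#'
#' @param tbl a phenotype tibble.
#' @param response name of the response column.
#' @param pair character length-2: the two levels, contrast = first minus
#'   second.
#' @param factor factor containing the levels.
#' @return one-row tibble: `contrast`, `estimate`, `se`, `df`, `statistic`,
#'   `p.value`.
#' @export
planned_contrast <- function(tbl, response, pair, factor = "inoculum") {
  stopifnot(length(pair) == 2)
  df <- pheno_model_frame(tbl, response, c("inoculum", "genotype", "block"))
  lev <- levels(df[[factor]])
  if (!all(pair %in% lev)) {
    stop("levels not present: ", paste(setdiff(pair, lev), collapse = ", "),
         call. = FALSE)
  }
  m <- stats::lm(.y ~ inoculum + genotype + block, data = df)
  if (requireNamespace("emmeans", quietly = TRUE)) {
    emm <- emmeans::emmeans(m, specs = factor)
    w <- stats::setNames(rep(0, length(lev)), lev)
    w[pair] <- c(1, -1)
    res <- summary(emmeans::contrast(emm, method = list(planned = unname(w)),
                                     adjust = "none"))
    tibble::tibble(contrast = paste(pair, collapse = " - "),
                   estimate = res$estimate, se = res$SE, df = res$df,
                   statistic = res$t.ratio, p.value = res$p.value)
  } else {
    # adjusted level means via the model's coefficient contrast
    X <- stats::model.matrix(m)
    mm <- function(level) {
      d2 <- df
      d2[[factor]] <- base::factor(level, levels = lev)
      colMeans(stats::model.matrix(stats::terms(m), data = d2))
    }
    L <- mm(pair[1]) - mm(pair[2])
    est <- sum(L * stats::coef(m))
    se <- sqrt(drop(t(L) %*% stats::vcov(m) %*% L))
    dfree <- m$df.residual
    tstat <- est / se
    tibble::tibble(contrast = paste(pair, collapse = " - "),
                   estimate = est, se = se, df = dfree, statistic = tstat,
                   p.value = 2 * stats::pt(-abs(tstat), dfree))
  }
}
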