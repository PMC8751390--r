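#' Simulate a full two-experiment study
#'
#' Generates, from one seed, a complete synthetic study: the rhizosphere
#' sequencing experiment (count table, metadata, placeholder taxonomy,
#' ground truth) and, optionally, the microbiome-feedback phenotype
#' experiment with additive inoculum effects.
#'
#' @param spec a [synthetic_spec()].
#' @param inoculum_effects named numeric vector of additive biomass effects
#'   per inoculum (e.g. `c("Col-4x" = -10)`), or `NULL` to skip phenotypes.
#' @param phenotype_noise_sd residual SD of the phenotype responses.
#' @param n_per_cell phenotype replicates per genotype x inoculum x block.
#' @return list with `counts`, `metadata`, `taxonomy`, `phenotypes`
#'   (or `NULL`), `truth`, and `spec`.
#' @export
simulate_experiment <- function(spec = synthetic_spec(),
                                inoculum_effects = NULL,
                                phenotype_noise_sd = 5,
                                n_per_cell = 2) {
  truth <- generate_truth(spec)
  sim <- simulate_counts(truth, spec)
  phen <- NULL
  if (!is.null(inoculum_effects)) {
    phen <- simulate_phenotypes(inoculum_effects = inoculum_effects,
                                noise_sd = phenotype_noise_sd,
                                n_per_cell = n_per_cell, seed = spec$seed)
    below <- simulate_phenotypes(inoculum_effects = inoculum_effects / 2,
                                 grand_mean = 25,
                                 noise_sd = phenotype_noise_sd / 2,
                                 n_per_cell = n_per_cell,
                                 response = "belowground_biomass",
                                 seed = spec$seed + 1L)
    phen$belowground_biomass <- below$belowground_biomass
  }
  list(counts = sim$counts, metadata = sim$metadata,
       taxonomy = synthetic_taxonomy(taxon_ids(sim$counts)),
       phenotypes = phen, truth = truth, spec = spec)
}

#' Write a simulated study to disk
#'
#' Writes the count table (TSV + provenance sidecar), metadata CSV,
#' taxonomy TSV, phenotype CSV (if present) and a ground-truth JSON to a
#' directory.  Outputs are byte-identical across runs with the same
#' experiment object.
#'
#' @param experiment a list from [simulate_experiment()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty: ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(experiment$counts, file.path(dir, "counts.tsv"))
  utils::write.csv(experiment$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(experiment$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(experiment$phenotypes)) {
    utils::write.csv(experiment$phenotypes, file.path(dir, "phenotypes.csv"),
                     row.names = FALSE)
  }
  tr <- experiment$truth
  jsonlite::write_json(
    list(seed = experiment$spec$seed, theta = tr$theta,
         effects = tr$effects,
         pi = stats::setNames(split(tr$pi, row(tr$pi)), rownames(tr$pi))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' End-to-end analysis of a rhizosphere study
#'
#' Runs the full analysis on a count table: optional non-target and
#' total-read filtering, the three standard Dirichlet-multinomial
#' comparisons with convergence diagnostics, the PERMANOVA summary table
#' on Jaccard and Bray-Curtis dissimilarities, principal-coordinate
#' analysis, Shannon diversity with Welch tests, and (when a phenotype
#' table is supplied) the three-way ANOVA / Tukey HSD / planned-contrast
#' suite on each biomass response.
#'
#' @param counts a count table tibble.
#' @param metadata a metadata tibble.
#' @param taxonomy optional taxonomy tibble; when given, non-target taxa
#'   are removed first.
#' @param phenotypes optional phenotype tibble.
#' @param settings a [dmm_settings()].
#' @param min_total_reads optional threshold for [filter_min_total_reads()]
#'   (`NULL` = keep all taxa).
#' @param n_perm PERMANOVA permutations.
#' @param phenotype_responses response columns to analyse when phenotypes
#'   are present.
#' @return a `rhizo_report` list: `comparisons` (a `dmm_comparisons`),
#'   `diagnostics` (R-hat summary per contrast), `permanova`, `pcoa`,
#'   `shannon`, `phenotype` (per response: `anova`, `tukey`, `contrasts`,
#'   `residual_summary`), and `log` (seed, settings, dataset sizes,
#'   timings).
#' @export
analyze_experiment <- function(counts, metadata, taxonomy = NULL,
                               phenotypes = NULL, settings = dmm_settings(),
                               min_total_reads = NULL, n_perm = 999,
                               phenotype_responses = c("aboveground_biomass",
                                                       "belowground_biomass")) {
  t0 <- proc.time()[["elapsed"]]
  log <- list(seed = settings$seed,
              settings = unclass(settings),
              n_samples_in = nrow(counts), n_taxa_in = ncol(counts) - 1L)
  if (!is.null(taxonomy)) counts <- filter_nontarget_taxa(counts, taxonomy)
  if (!is.null(min_total_reads)) {
    counts <- filter_min_total_reads(counts, min_total_reads)
  }
  log$n_taxa_analyzed <- ncol(counts) - 1L
  validate_count_table(counts, require_positive_depth = TRUE)

  comparisons <- standard_comparisons(counts, metadata, settings)
  diagnostics <- purrr::imap_dfr(comparisons, function(x, nm) {
    rh <- gelman_rubin(x$fit)
    tibble::tibble(contrast = nm, max_rhat = max(rh$rhat, na.rm = TRUE),
                   frac_rhat_below_1.1 = mean(rh$rhat < 1.1, na.rm = TRUE),
                   mean_accept = mean(x$fit$accept_rate))
  })

  perm <- permanova_table(counts, metadata, n_perm = n_perm,
                          seed = settings$seed)
  meta_o <- metadata[match(counts$sample_id, metadata$sample_id), ]
  planted <- counts[!meta_o$is_soil_control, , drop = FALSE]
  ord <- pcoa(jaccard(planted))
  shan <- shannon_summary(counts, metadata)

  phen <- NULL
  if (!is.null(phenotypes)) {
    phen <- purrr::map(
      stats::setNames(phenotype_responses, phenotype_responses),
      function(resp) {
        list(anova = fit_anova3(phenotypes, resp),
             tukey = tukey_hsd(phenotypes, resp, "inoculum"),
             contrasts = dplyr::bind_rows(
               planned_contrast(phenotypes, resp, c("Col-2x", "Col-4x")),
               planned_contrast(phenotypes, resp, c("Ler-2x", "Ler-4x"))),
             residual_summary = residual_summary(phenotypes, resp))
      })
  }
  log$elapsed_s <- proc.time()[["elapsed"]] - t0
  structure(list(comparisons = comparisons, diagnostics = diagnostics,
                 permanova = perm, pcoa = ord, shannon = shan,
                 phenotype = phen, counts = counts, metadata = metadata,
                 log = log),
            class = "rhizo_report")
}

#' @export
print.rhizo_report <- function(x, ...) {
  cat("Rhizosphere community analysis (seed", x$log$seed, ")\n")
  cat(sprintf("  %d samples, %d taxa analysed\n", x$log$n_samples_in,
              x$log$n_taxa_analyzed))
  print(x$comparisons)
  cat("PERMANOVA summary:\n")
  print(x$permanova, n = Inf)
  cat(sprintf("Shannon diversity: mean %.3f (+/- %.3f SE, n = %d)\n",
              x$shannon$mean, x$shannon$se, x$shannon$n))
  if (!is.null(x$phenotype)) {
    for (nm in names(x$phenotype)) {
      a <- x$phenotype[[nm]]$anova
      cat(sprintf("ANOVA %s: inoculum p = %.3g\n", nm,
                  a$p.value[a$term == "inoculum"]))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits per-contrast differential-abundance TSVs, the PERMANOVA and
#' diversity summaries, phenotype tables, a diagnostics JSON (R-hat and
#' acceptance summaries) and a run-log JSON recording seed and settings.
#'
#' @param report a `rhizo_report`.
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty: ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
  for (nm in names(report$comparisons)) {
    wtsv(report$comparisons[[nm]]$result,
         paste0("differential_abundance_", nm, ".tsv"))
  }
  wtsv(report$permanova, "permanova.tsv")
  wtsv(report$shannon$per_sample, "shannon_per_sample.tsv")
  wtsv(report$shannon$tests, "shannon_tests.tsv")
  wtsv(report$pcoa$coordinates, "pcoa_coordinates.tsv")
  if (!is.null(report$phenotype)) {
    for (nm in names(report$phenotype)) {
      p <- report$phenotype[[nm]]
      wtsv(p$anova, paste0("anova_", nm, ".tsv"))
      wtsv(p$tukey$comparisons, paste0("tukey_", nm, ".tsv"))
      wtsv(p$tukey$letters, paste0("tukey_letters_", nm, ".tsv"))
      wtsv(p$contrasts, paste0("planned_contrasts_", nm, ".tsv"))
      wtsv(p$residual_summary, paste0("residuals_by_inoculum_", nm, ".tsv"))
    }
  }
  jsonlite::write_json(list(diagnostics = report$diagnostics),
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery, calibration and power study
#'
#' Repeats simulate-and-fit over `n_datasets` independent synthetic
#' datasets with two groups ("A" and "B"; any effects in the spec should
#' target group "B") and reports, per dataset: the maximum absolute error
#' of posterior-mean compositions for taxa with true abundance above
#' `abund_floor`, the coverage of 95% equal-tailed intervals, the flagged
#' fraction among truly null taxa (decision-rule calibration), and whether
#' every planted effect taxon was flagged (power).
#'
#' @param n_datasets number of replicate datasets.
#' @param spec a [synthetic_spec()] template; its `replicates` should name
#'   groups `A` and `B` (the default here), and its seed seeds dataset 1.
#' @param settings a [dmm_settings()].
#' @param abund_floor truth threshold for the error summary.
#' @param effect_target_abund,effect_fold when both are given, each
#'   dataset's spec is re-planted via [effects_at_abundance()] with this
#'   fold change on the second group's taxon nearest the target abundance
#'   (power studies on a chosen abundance stratum).
#' @return tibble with one row per dataset: `dataset`, `mean_abs_err`,
#'   `max_abs_err`, `coverage`, `flagged_frac_null`, `n_effect_taxa`,
#'   `all_effects_flagged`.
#' @export
run_recovery_study <- function(n_datasets = 20,
                               spec = synthetic_spec(
                                 replicates = c(A = 8, B = 8), n_soil = 0),
                               settings = dmm_settings(),
                               abund_floor = 0.005,
                               effect_target_abund = NULL,
                               effect_fold = NULL) {
  groups <- names(spec$replicates)
  stopifnot(length(groups) == 2)
  purrr::map_dfr(seq_len(n_datasets), function(r) {
    sp <- spec
    sp$seed <- spec$seed + (r - 1L) * 10L
    if (!is.null(effect_target_abund) && !is.null(effect_fold)) {
      sp <- effects_at_abundance(sp, groups[2], effect_fold,
                                 target = effect_target_abund)
    }
    truth <- generate_truth(sp)
    sim <- simulate_counts(truth, sp)
    st <- settings
    st$seed <- settings$seed + r
    fit <- fit_dmm(sim$counts, stats::setNames(sim$metadata$group,
                                               sim$metadata$sample_id), st)
    # per-taxon posterior means and intervals per group
    errs <- cover <- c()
    for (g in groups) {
      draws <- pooled_pi(fit, g)
      pm <- colMeans(draws)
      qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
      tr <- truth$pi[g, ]
      errs <- c(errs, abs(pm - tr)[tr > abund_floor])
      cover <- c(cover, tr >= qs[1, ] & tr <= qs[2, ])
    }
    res <- compare_groups(fit, groups[1], groups[2])
    eff_idx <- unique(sp$effects$taxon)
    null_idx <- setdiff(seq_along(fit$taxa), eff_idx)
    tibble::tibble(
      dataset = r,
      mean_abs_err = if (length(errs)) mean(errs) else NA_real_,
      max_abs_err = if (length(errs)) max(errs) else NA_real_,
      coverage = mean(cover),
      flagged_frac_null = mean(res$flagged[null_idx]),
      n_effect_taxa = length(eff_idx),
      all_effects_flagged = if (length(eff_idx)) all(res$flagged[eff_idx]) else NA)
  })
}
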