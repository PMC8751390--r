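#' Specify a synthetic rhizosphere experiment
#'
#' Defines the generative conditions for a Dirichlet-multinomial community
#' simulation mirroring a genotype-x-ploidy rhizosphere study: a baseline
#' composition drawn from a symmetric Dirichlet, group compositions derived
#' by multiplicative fold-change effects on chosen taxa (renormalised),
#' replicate compositions drawn from `Dirichlet(theta * pi)`, and multinomial
#' read counts at uniformly drawn sequencing depths.
#'
#' Defaults mirror the emulated study design: four planted groups (Col-2x,
#' Col-4x, Ler-2x, Ler-4x) with 8 replicates each, 7 unplanted soil
#' controls with their own community, and per-sample depths drawn uniformly
#' on 36,033..143,254 reads.  `n_taxa` defaults to a desk-scale 50 and can
#' be raised towards the study's 2,689 ASVs.
#'
#' @param n_taxa number of taxa (ASVs) K.
#' @param replicates named integer vector: replicates per planted group.
#' @param n_soil number of unplanted soil-control samples (0 to disable).
#' @param base_concentration symmetric Dirichlet concentration for the
#'   baseline composition; values below 1 give realistically uneven
#'   rank-abundance curves.
#' @param theta Dirichlet-multinomial intensity `theta_true` controlling
#'   replicate-to-replicate overdispersion around the group composition
#'   (larger = less overdispersed).
#' @param effects a data frame with columns `taxon` (index in 1..K),
#'   `group` (a planted group label) and `fold` (multiplicative change > 0),
#'   or `NULL` for a null community.
#' @param depth_range integer length-2: inclusive bounds for per-sample
#'   sequencing depth.
#' @param seed integer seed from which all generator substreams
#'   (composition, depths, counts, phenotypes) are derived.
#' @return an object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_taxa = 20, seed = 1)
#' truth <- generate_truth(spec)
#' sim <- simulate_counts(truth, spec)
#' @export
synthetic_spec <- function(n_taxa = 50,
                           replicates = c("Col-2x" = 8, "Col-4x" = 8,
                                          "Ler-2x" = 8, "Ler-4x" = 8),
                           n_soil = 7,
                           base_concentration = 0.3,
                           theta = 500,
                           effects = NULL,
                           depth_range = c(36033L, 143254L),
                           seed = 1L) {
  stopifnot(n_taxa >= 2, all(replicates >= 1), length(replicates) >= 1,
            n_soil >= 0, base_concentration > 0, theta > 0,
            depth_range[1] <= depth_range[2], depth_range[1] >= 1)
  if (is.null(names(replicates)) || any(names(replicates) == "")) {
    stop("replicates must be a named vector of planted groups", call. = FALSE)
  }
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    stopifnot(all(c("taxon", "group", "fold") %in% names(effects)))
    if (any(effects$taxon < 1 | effects$taxon > n_taxa)) {
      stop("effect taxon index out of range 1..", n_taxa, call. = FALSE)
    }
    if (any(effects$fold <= 0)) stop("fold changes must be > 0", call. = FALSE)
    if (!all(effects$group %in% names(replicates))) {
      stop("effect group not among planted groups: ",
           paste(setdiff(effects$group, names(replicates)), collapse = ", "),
           call. = FALSE)
    }
  } else {
    effects <- tibble::tibble(taxon = integer(), group = character(),
                              fold = numeric())
  }
  structure(
    list(n_taxa = as.integer(n_taxa), replicates = replicates,
         n_soil = as.integer(n_soil),
         base_concentration = base_concentration, theta = theta,
         effects = effects, depth_range = as.integer(depth_range),
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Named substreams: each generation stage reseeds from the spec seed plus a
# fixed stage offset, so any stage is reproducible independently of the others.
stage_seed <- function(seed, stage) {
  offs <- c(composition = 1L, soil = 2L, depths = 3L, counts = 4L,
            phenotypes = 5L)
  (abs(as.integer(seed)) %% 2000000000L) + offs[[stage]]
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x <- pmax(x, 1e-300)
  x / sum(x)
}

#' Generate the ground truth for a synthetic experiment
#'
#' Draws the baseline composition from a symmetric Dirichlet, applies the
#' spec's multiplicative effects per group with renormalisation, and draws
#' an independent soil-control composition.  Deterministic given the spec
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_truth`: list with `pi` (groups x
#'   taxa matrix of true compositions, including a `"soil"` row when soil
#'   controls are requested), `theta`, `effects`, and `baseline`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, "composition"))
  K <- spec$n_taxa
  baseline <- rdirichlet1(rep(spec$base_concentration, K))
  groups <- names(spec$replicates)
  pi <- matrix(rep(baseline, each = length(groups)), nrow = length(groups),
               dimnames = list(groups, sprintf("ASV%04d", seq_len(K))))
  for (r in seq_len(nrow(spec$effects))) {
    g <- spec$effects$group[r]
    pi[g, spec$effects$taxon[r]] <- pi[g, spec$effects$taxon[r]] * spec$effects$fold[r]
  }
  pi <- sweep(pi, 1, rowSums(pi), "/")
  if (spec$n_soil > 0) {
    set.seed(stage_seed(spec$seed, "soil"))
    soil <- rdirichlet1(rep(spec$base_concentration, K))
    pi <- rbind(pi, soil = soil)
  }
  structure(list(pi = pi, theta = spec$theta, effects = spec$effects,
                 baseline = baseline),
            class = "synthetic_truth")
}

#' True log10 fold changes between two groups
#'
#' @param truth a `synthetic_truth`.
#' @param g1,g2 group labels (rows of `truth$pi`); each may also be a vector
#'   of groups, in which case the pooled (averaged) composition is used.
#' @return tibble with `taxon`, `log10_fc` (`log10(pi_g1 / pi_g2)`).
#' @export
true_log10_fc <- function(truth, g1, g2) {
  p1 <- colMeans(truth$pi[g1, , drop = FALSE])
  p2 <- colMeans(truth$pi[g2, , drop = FALSE])
  tibble::tibble(taxon = colnames(truth$pi), log10_fc = unname(log10(p1 / p2)))
}

#' Plant effects on taxa near a target abundance
#'
#' Replaces the spec's effect list with multiplicative effects on the
#' `n_effects` baseline taxa whose true relative abundance is closest to
#' `target` (e.g. fold changes planted on ~0.5%-abundance taxa).  Because
#' the baseline composition depends only on the spec seed's composition
#' substream, adding effects does not change which taxa are selected.
#'
#' @param spec a [synthetic_spec()].
#' @param group planted group receiving the effect.
#' @param fold multiplicative fold change (> 0).
#' @param target baseline relative abundance to aim for.
#' @param n_effects number of taxa to hit.
#' @return the spec with its `effects` replaced.
#' @export
effects_at_abundance <- function(spec, group, fold, target = 0.005,
                                 n_effects = 1) {
  base <- spec
  base$effects <- tibble::tibble(taxon = integer(), group = character(),
                                 fold = numeric())
  baseline <- generate_truth(base)$baseline
  idx <- order(abs(baseline - target))[seq_len(n_effects)]
  spec$effects <- tibble::tibble(taxon = as.integer(idx), group = group,
                                 fold = fold)
  spec
}

#' Simulate read counts from a synthetic truth
#'
#' For each replicate of each group (and each soil control), draws the
#' replicate composition `p ~ Dirichlet(theta * pi_group)`, a sequencing
#' depth uniform on the spec's depth range, and multinomial counts.
#'
#' @param truth a `synthetic_truth` from [generate_truth()].
#' @param spec the [synthetic_spec()] used to build it.
#' @return list with `counts` (a count table tibble) and `metadata`
#'   (a tibble with `sample_id`, `genotype`, `ploidy`, `block`, `group`,
#'   `is_soil_control`).
#' @export
simulate_counts <- function(truth, spec) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(spec, "synthetic_spec"))
  groups <- names(spec$replicates)
  reps <- c(spec$replicates,
            if (spec$n_soil > 0) stats::setNames(spec$n_soil, "soil"))
  ids <- unlist(lapply(names(reps), function(g) {
    sprintf("%s.r%02d", gsub("-", "", g), seq_len(reps[[g]]))
  }))
  n <- length(ids)
  set.seed(stage_seed(spec$seed, "depths"))
  depths <- sample.int(spec$depth_range[2] - spec$depth_range[1] + 1L, n,
                       replace = TRUE) + spec$depth_range[1] - 1L
  set.seed(stage_seed(spec$seed, "counts"))
  m <- matrix(0L, n, spec$n_taxa, dimnames = list(ids, colnames(truth$pi)))
  i <- 0L
  for (g in names(reps)) {
    alpha <- truth$theta * truth$pi[g, ]
    for (j in seq_len(reps[[g]])) {
      i <- i + 1L
      p <- rdirichlet1(alpha)
      m[i, ] <- stats::rmultinom(1, depths[i], p)[, 1]
    }
  }
  grp <- rep(names(reps), times = reps)
  # genotype/ploidy are recoverable only for labels of the "<genotype>-<n>x"
  # form; generic group names (e.g. "A", "B") keep the label as-is
  std <- grepl("^[^-]+-[0-9]+x$", grp)
  meta <- tibble::tibble(
    sample_id = ids,
    genotype = ifelse(std, sub("-.*$", "", grp), NA_character_),
    ploidy = ifelse(std, sub("^.*-", "", grp), NA_character_),
    block = as.character(rep_len(1:4, n)),
    group = grp,
    is_soil_control = grp == "soil")
  ct <- as_count_table(m)
  ct <- prov_add(ct, "simulate_counts", seed = spec$seed,
                 theta = spec$theta, n_taxa = spec$n_taxa)
  list(counts = ct, metadata = meta)
}

#' Null-community convenience dataset
#'
#' A [synthetic_spec()] run with an empty effect list: every planted group
#' shares the same true composition.  Used by decision-rule calibration
#' studies.
#'
#' @param spec a [synthetic_spec()]; its `effects` are ignored.
#' @return list with `counts`, `metadata`, `truth`.
#' @export
make_null_dataset <- function(spec) {
  spec$effects <- tibble::tibble(taxon = integer(), group = character(),
                                 fold = numeric())
  truth <- generate_truth(spec)
  sim <- simulate_counts(truth, spec)
  c(sim, list(truth = truth))
}

#' Placeholder taxonomy for synthetic taxa
#'
#' Assigns each synthetic ASV a bacterial lineage with a phylum cycled from
#' a fixed set of common soil phyla; purely a synthetic stand-in so that
#' rank aggregation and filtering can be exercised on generated data.
#'
#' @param taxon_ids character vector of taxon identifiers.
#' @return a taxonomy tibble with non-target flags (all `FALSE`).
#' @export
synthetic_taxonomy <- function(taxon_ids) {
  phyla <- c("Proteobacteria", "Acidobacteria", "Actinobacteria",
             "Bacteroidetes", "Firmicutes", "Verrucomicrobia")
  flag_nontarget(tibble::tibble(
    taxon_id = taxon_ids,
    kingdom = "Bacteria",
    phylum = rep_len(phyla, length(taxon_ids)),
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = NA_character_))
}

#' Simulate plant-performance phenotypes
#'
#' Generates a fully factorial microbiome-feedback experiment: plants of
#' each genotype grown in substrate inoculated with each conditioned
#' microbiome, in blocks, with additive genotype, inoculum and block
#' effects plus Gaussian noise:
#' `response = grand_mean + genotype + inoculum + block + N(0, noise_sd)`.
#'
#' @param genotypes,inocula factor levels for host genotype and soil
#'   inoculum (default: the four genotype-ploidy groups for both).
#' @param n_per_cell replicates per genotype-x-inoculum-x-block cell.
#' @param n_blocks number of experimental blocks.
#' @param grand_mean baseline response (e.g. mg biomass).
#' @param genotype_effects,inoculum_effects,block_effects named numeric
#'   vectors of additive effects; unnamed levels get 0.
#' @param noise_sd residual standard deviation.
#' @param response name of the response column.
#' @param seed integer seed.
#' @return a phenotype tibble (`plant_id`, `genotype`, `inoculum`, `block`,
#'   response) with the effect specification stored in the `"truth"`
#'   attribute.
#' @export
simulate_phenotypes <- function(genotypes = c("Col-2x", "Col-4x", "Ler-2x", "Ler-4x"),
                                inocula = genotypes,
                                n_per_cell = 2, n_blocks = 4,
                                grand_mean = 50,
                                genotype_effects = NULL,
                                inoculum_effects = NULL,
                                block_effects = NULL,
                                noise_sd = 5,
                                response = "aboveground_biomass",
                                seed = 1L) {
  eff <- function(levels, x) {
    out <- stats::setNames(rep(0, length(levels)), levels)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  blocks <- as.character(seq_len(n_blocks))
  ge <- eff(genotypes, genotype_effects)
  ie <- eff(inocula, inoculum_effects)
  be <- eff(blocks, block_effects)
  design <- expand.grid(rep = seq_len(n_per_cell), block = blocks,
                        inoculum = inocula, genotype = genotypes,
                        stringsAsFactors = FALSE)
  set.seed(stage_seed(seed, "phenotypes"))
  y <- grand_mean + ge[design$genotype] + ie[design$inoculum] +
    be[design$block] + stats::rnorm(nrow(design), 0, noise_sd)
  out <- tibble::tibble(
    plant_id = sprintf("plant%04d", seq_len(nrow(design))),
    genotype = design$genotype, inoculum = design$inoculum,
    block = design$block)
  out[[response]] <- unname(y)
  attr(out, "truth") <- list(grand_mean = grand_mean, genotype_effects = ge,
                             inoculum_effects = ie, block_effects = be,
                             noise_sd = noise_sd, response = response)
  out
}
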