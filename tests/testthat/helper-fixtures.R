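# small fixtures built in code

tiny_count_matrix <- function() {
  matrix(c(5, 0, 2, 3,
           1, 4, 0, 2,
           2, 2, 2, 2), nrow = 3, byrow = TRUE,
         dimnames = list(c("s1", "s2", "s3"), c("t1", "t2", "t3", "t4")))
}

tiny_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3", "t4", "t5"),
    kingdom = c("Bacteria", "Bacteria", "Eukaryota", "Bacteria", NA),
    phylum = c("Proteobacteria", "Cyanobacteria", NA, "Firmicutes", "X"),
    class = c("Alpha", "Chloroplastia", NA, NA, NA),
    order = c(NA, "Chloroplast", NA, NA, NA),
    family = c("Rhizobiaceae", NA, NA, NA, NA),
    genus = NA_character_, species = NA_character_)
}

standard_metadata <- function(reps = 2, soil = 2) {
  groups <- c("Col-2x", "Col-4x", "Ler-2x", "Ler-4x")
  tibble::tibble(
    sample_id = c(sprintf("p%02d", seq_len(4 * reps)),
                  sprintf("soil%02d", seq_len(soil))),
    genotype = c(rep(c("Col", "Col", "Ler", "Ler"), each = reps),
                 rep(NA, soil)),
    ploidy = c(rep(c("2x", "4x", "2x", "4x"), each = reps), rep(NA, soil)),
    block = "1") |>
    (\(m) rhizodmm:::build_metadata(m))()
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deterministic small two-group dataset for sampler tests
small_two_group <- function(K = 20, reps = 6, theta = 200, seed = 11,
                            effects = NULL, depth = c(3000L, 8000L)) {
  spec <- synthetic_spec(n_taxa = K, replicates = c(A = reps, B = reps),
                         n_soil = 0, theta = theta, depth_range = depth,
                         effects = effects, seed = seed)
  truth <- generate_truth(spec)
  sim <- simulate_counts(truth, spec)
  list(spec = spec, truth = truth, counts = sim$counts,
       metadata = sim$metadata,
       groups = stats::setNames(sim$metadata$group, sim$metadata$sample_id))
}
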