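#' Read a taxonomy table
#'
#' Imports an ASV taxonomy table (tab-delimited; first column = taxon id,
#' then the seven ranks kingdom..species, extra columns ignored) and derives
#' the non-target flags used by [filter_nontarget_taxa()].  Unassigned ranks
#' may be empty, `NA`, or the literal string `"NA"`; all are stored as `NA`.
#'
#' @param path TSV file path.
#' @return a tibble with `taxon_id`, the rank columns, and logical columns
#'   `is_chloroplast`, `is_mitochondrion`, `is_eukaryote`,
#'   `kingdom_unassigned`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  names(df)[1] <- "taxon_id"
  if (anyDuplicated(df$taxon_id)) {
    stop("duplicate taxon identifiers in ", path, call. = FALSE)
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  for (r in setdiff(ranks, names(df))) df[[r]] <- NA_character_
  flag_nontarget(tibble::as_tibble(df[, c("taxon_id", ranks)]))
}

#' Flag non-target lineages
#'
#' Derives, deterministically from the lineage strings, the standard 16S
#' non-target flags: chloroplast (any rank named "Chloroplast"),
#' mitochondrion (any rank named "Mitochondria"/"Mitochondrion"), eukaryote
#' (kingdom "Eukaryota"/"Eukarya"), and kingdom-level unassignment.
#'
#' @param tax a tibble with `taxon_id` and rank columns.
#' @return `tax` with the four logical flag columns appended/replaced.
#' @export
flag_nontarget <- function(tax) {
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family",
                       "genus", "species"), names(tax))
  rk <- as.matrix(tax[, ranks, drop = FALSE])
  rk[rk == "NA" | rk == ""] <- NA
  has <- function(values) {
    rowSums(matrix(rk %in% values, nrow = nrow(rk)), na.rm = TRUE) > 0
  }
  tax$is_chloroplast <- has("Chloroplast")
  tax$is_mitochondrion <- has(c("Mitochondria", "Mitochondrion"))
  kingdom <- if ("kingdom" %in% ranks) rk[, "kingdom"] else rep(NA_character_, nrow(rk))
  tax$is_eukaryote <- !is.na(kingdom) & kingdom %in% c("Eukaryota", "Eukarya")
  tax$kingdom_unassigned <- is.na(kingdom)
  tax
}

#' Read sample metadata
#'
#' Imports the sample sheet for a genotype-x-ploidy rhizosphere experiment:
#' columns `sample_id`, `genotype` (`Col`/`Ler`, empty for unplanted soil
#' controls), `ploidy` (`2x`/`4x`, empty for controls), and `block`.  The
#' group label (`Col-2x`, ..., `soil`) and the `is_soil_control` flag are
#' derived, never read.
#'
#' @param path CSV or TSV file path (delimiter inferred from extension).
#' @return a tibble with `sample_id`, `genotype`, `ploidy`, `block`,
#'   `group`, `is_soil_control`.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  }
  for (col in c("genotype", "ploidy", "block")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  build_metadata(tibble::as_tibble(df[, c("sample_id", "genotype", "ploidy", "block")]))
}

build_metadata <- function(meta) {
  soil <- is.na(meta$genotype) & is.na(meta$ploidy)
  if (any(xor(is.na(meta$genotype), is.na(meta$ploidy)))) {
    stop("genotype and ploidy must both be present (planted) or both absent (soil control)",
         call. = FALSE)
  }
  meta$group <- ifelse(soil, "soil", paste(meta$genotype, meta$ploidy, sep = "-"))
  meta$is_soil_control <- soil
  meta
}

#' Derive two-group labels for the standard contrasts
#'
#' Maps sample metadata onto the binary grouping each standard comparison
#' fits: `"ploidy"` (all 2x vs all 4x), `"genotype"` (Col vs Ler), and
#' `"col4x"` (Col-4x vs the other three planted groups pooled).  Soil
#' controls receive `NA` and are excluded from the fits.
#'
#' @param meta a metadata tibble (see [read_metadata()]).
#' @param contrast one of `"ploidy"`, `"genotype"`, `"col4x"`.
#' @return a character vector of group labels aligned with `meta$sample_id`.
#' @export
contrast_groups <- function(meta, contrast = c("ploidy", "genotype", "col4x")) {
  contrast <- match.arg(contrast)
  g <- rep(NA_character_, nrow(meta))
  planted <- !meta$is_soil_control
  g[planted] <- switch(contrast,
    ploidy   = meta$ploidy[planted],
    genotype = meta$genotype[planted],
    col4x    = ifelse(meta$group[planted] == "Col-4x", "Col-4x", "others"))
  g
}
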