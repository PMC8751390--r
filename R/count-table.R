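#' Count tables
#'
#' A count table is an ordinary wide tibble: one row per sample, a
#' `sample_id` character column first, and one non-negative integer column per
#' taxon (ASV).  All `rhizodmm` functions take and return this shape, so count
#' tables pipe through `dplyr` verbs like any other data frame.  A provenance
#' log (the sequence of filters applied, with parameters) travels along as the
#' `"provenance"` attribute and is written out as a JSON sidecar by
#' [write_count_table()].
#'
#' @param x a matrix (samples x taxa, with dimnames) or a data frame whose
#'   first column holds sample identifiers.
#' @return a tibble with `sample_id` first and one numeric column per taxon.
#' @examples
#' ct <- as_count_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' sample_depths(ct)
#' @export
as_count_table <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    ct <- tibble::as_tibble(x, .name_repair = "minimal")
    ct <- tibble::add_column(ct, sample_id = rownames(x), .before = 1)
  } else {
    ct <- tibble::as_tibble(x)
    names(ct)[1] <- "sample_id"
    ct$sample_id <- as.character(ct$sample_id)
  }
  validate_count_table(ct)
  ct
}

#' @rdname as_count_table
#' @param ct a count table tibble.
#' @export
count_matrix <- function(ct) {
  m <- as.matrix(ct[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ct$sample_id
  m
}

#' @rdname as_count_table
#' @export
sample_depths <- function(ct) {
  stats::setNames(rowSums(count_matrix(ct)), ct$sample_id)
}

#' @rdname as_count_table
#' @export
taxon_ids <- function(ct) names(ct)[-1]

#' Validate a count table
#'
#' Checks the invariants every count table must satisfy: unique sample and
#' taxon identifiers, non-negative integer-valued counts, and (optionally)
#' strictly positive sequencing depth for every sample.
#'
#' @param ct a count table tibble (see [as_count_table()]).
#' @param require_positive_depth error if any sample has depth 0.
#' @return `ct`, invisibly, if valid; otherwise an error.
#' @export
validate_count_table <- function(ct, require_positive_depth = FALSE) {
  if (!is.data.frame(ct) || ncol(ct) < 2) {
    stop("a count table needs a sample_id column plus at least one taxon", call. = FALSE)
  }
  if (anyDuplicated(ct$sample_id)) {
    stop("duplicate sample identifiers: ",
         paste(unique(ct$sample_id[duplicated(ct$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(ct))) {
    stop("duplicate taxon identifiers: ",
         paste(unique(names(ct)[duplicated(names(ct))]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(ct[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop("counts must be numeric and complete", call. = FALSE)
  }
  bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-integer count at sample '%s', taxon '%s' (value %g)",
                 ct$sample_id[bad[1, 1]], names(ct)[-1][bad[1, 2]], m[bad[1, , drop = FALSE]]),
         call. = FALSE)
  }
  if (require_positive_depth) {
    d <- rowSums(m)
    if (any(d <= 0)) {
      stop("zero sequencing depth for sample(s): ",
           paste(ct$sample_id[d <= 0], collapse = ", "), call. = FALSE)
    }
  }
  invisible(ct)
}

prov_get <- function(ct) attr(ct, "provenance") %||% list()

prov_add <- function(ct, step, ...) {
  p <- prov_get(ct)
  p[[length(p) + 1]] <- c(list(step = step), list(...))
  attr(ct, "provenance") <- p
  ct
}

#' Read and write count tables
#'
#' `read_count_table()` imports a samples-x-taxa read-count table from a
#' tab-delimited text file or a BIOM 1.0 (JSON) file.  TSV orientation is
#' never guessed: state whether rows are taxa (the usual ASV-table layout)
#' or samples.  `write_count_table()` writes the TSV form (samples as rows)
#' together with a JSON provenance sidecar at `<path>.provenance.json`
#' recording the filters applied so a run can be reproduced.
#'
#' @param path file to read or write.
#' @param format `"tsv"` or `"biom"` (BIOM 1.0 JSON dialect).
#' @param orientation for TSV input: `"taxa_rows"` (first column = taxon id,
#'   remaining columns = samples) or `"samples_rows"`.
#' @return `read_count_table()` returns a count table tibble;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             orientation = c("taxa_rows", "samples_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    ct <- as_count_table(t(m))
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed TSV (need id column + data): ", path, call. = FALSE)
    num <- df[, -1, drop = FALSE]
    for (j in seq_along(num)) {
      v <- num[[j]]
      if (!is.numeric(v)) {
        vv <- suppressWarnings(as.numeric(v))
        if (anyNA(vv)) {
          stop(sprintf("parse error in '%s', column '%s': non-numeric value '%s'",
                       path, names(num)[j], v[which(is.na(vv))[1]]), call. = FALSE)
        }
        num[[j]] <- vv
      }
    }
    m <- as.matrix(num)
    rownames(m) <- as.character(df[[1]])
    if (orientation == "taxa_rows") m <- t(m)
    ct <- as_count_table(m)
  }
  prov_add(ct, "read_count_table", path = path, format = format)
}

#' @rdname read_count_table
#' @param ct a count table tibble.
#' @param sidecar write the JSON provenance sidecar (default `TRUE`).
#' @export
write_count_table <- function(ct, path, sidecar = TRUE) {
  validate_count_table(ct)
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(file = basename(path),
           n_samples = nrow(ct), n_taxa = ncol(ct) - 1L, provenance = prov_get(ct)),
      paste0(path, ".provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Remove non-target taxa
#'
#' Drops ASVs classified as chloroplast, mitochondrion or eukaryote, and ASVs
#' with no kingdom-level classification.  ASVs that are unassigned ("NA") at
#' any rank *below* kingdom are retained.
#'
#' @param ct a count table tibble.
#' @param tax a taxonomy tibble from [read_taxonomy()] or [flag_nontarget()].
#' @return the filtered count table (same samples, fewer taxa).
#' @export
filter_nontarget_taxa <- function(ct, tax) {
  validate_count_table(ct)
  if (!all(c("is_chloroplast", "is_mitochondrion", "is_eukaryote",
             "kingdom_unassigned") %in% names(tax))) {
    tax <- flag_nontarget(tax)
  }
  missing <- setdiff(taxon_ids(ct), tax$taxon_id)
  if (length(missing) > 0) {
    stop("taxa absent from taxonomy table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  flagged <- tax$taxon_id[tax$is_chloroplast | tax$is_mitochondrion |
                            tax$is_eukaryote | tax$kingdom_unassigned]
  keep <- setdiff(taxon_ids(ct), flagged)
  out <- ct[, c("sample_id", keep)]
  attr(out, "provenance") <- prov_get(ct)
  prov_add(out, "filter_nontarget_taxa",
           removed = length(taxon_ids(ct)) - length(keep), kept = length(keep))
}

#' Keep taxa exceeding a total-read threshold
#'
#' Retains taxa whose read total across *all* samples is strictly greater
#' than `threshold` (so `threshold = 100` keeps the ">100 reads" taxa; a
#' taxon totalling exactly 100 is removed).
#'
#' @param ct a count table tibble.
#' @param threshold non-negative integer; taxa with total reads `> threshold`
#'   are kept.
#' @return the filtered count table.
#' @export
filter_min_total_reads <- function(ct, threshold = 100) {
  validate_count_table(ct)
  stopifnot(threshold >= 0)
  tot <- colSums(count_matrix(ct))
  keep <- names(tot)[tot > threshold]
  out <- ct[, c("sample_id", keep)]
  attr(out, "provenance") <- prov_get(ct)
  prov_add(out, "filter_min_total_reads", threshold = threshold,
           removed = length(tot) - length(keep), kept = length(keep))
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its sequencing depth.  No rarefaction is
#' performed anywhere in the package; unequal depths are carried as-is.
#'
#' @param ct a count table tibble with positive depth in every sample.
#' @return a composition table: same shape, rows summing to 1.
#' @export
to_relative_abundance <- function(ct) {
  validate_count_table(ct, require_positive_depth = TRUE)
  m <- count_matrix(ct)
  comp <- as_composition(sweep(m, 1, rowSums(m), "/"))
  attr(comp, "provenance") <- prov_get(ct)
  prov_add(comp, "to_relative_abundance")
}

as_composition <- function(m) {
  ct <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(ct, sample_id = rownames(m), .before = 1)
}

#' Aggregate a composition table to a taxonomic rank
#'
#' Sums per-sample ASV relative abundances within each group at `rank`.
#' Following the plotting convention for phylum-level community barplots,
#' ASVs whose within-sample relative abundance falls below `min_rel_abund`
#' are dropped before aggregation (so with a positive threshold the
#' aggregated rows sum to at most 1).  ASVs unassigned at `rank` are pooled
#' into a literal `"NA"` bin.
#'
#' @param comp a composition table from [to_relative_abundance()].
#' @param tax a taxonomy tibble.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param min_rel_abund per-sample relative-abundance floor applied to ASVs
#'   before aggregation (default 0 = keep everything; 0.05 reproduces the
#'   barplot clarity filter).
#' @return a tibble with `sample_id` and one column per observed rank value.
#' @export
aggregate_by_rank <- function(comp, tax, rank = "phylum", min_rel_abund = 0) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  rank <- match.arg(rank, ranks)
  m <- count_matrix(comp)
  missing <- setdiff(colnames(m), tax$taxon_id)
  if (length(missing) > 0) {
    stop("taxa absent from taxonomy table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m[m < min_rel_abund] <- 0
  lab <- tax[[rank]][match(colnames(m), tax$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "NA"
  agg <- t(rowsum(t(m), group = lab))
  as_composition(agg[, order(colnames(agg)), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
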