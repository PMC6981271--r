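#' Construct and validate a study design
#'
#' A study design maps each sample (TSV count column) to one of the two
#' pull-down conditions — `"P"` (modified bait) or `"NP"` (control bait) —
#' and a biological replicate index. Downstream condition means are always
#' grouped through this table.
#'
#' @param sample_id Character vector of unique sample identifiers; these must
#'   match the count column names of the counts table.
#' @param condition Character vector, each element `"P"` or `"NP"`.
#' @param replicate Positive integer vector, replicate index within condition.
#'
#' @return A tibble of class `study_design` with columns `sample_id`,
#'   `condition` (factor with levels `P`, `NP`) and `replicate`.
#'
#' @examples
#' study_design(c("P1", "P2", "P3", "NP1", "NP2", "NP3"),
#'              rep(c("P", "NP"), each = 3), rep(1:3, 2))
#' @export
study_design <- function(sample_id, condition, replicate) {
  stopifnot(length(sample_id) == length(condition),
            length(sample_id) == length(replicate))
  if (anyDuplicated(sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if (!all(condition %in% c("P", "NP"))) {
    stop("condition must be 'P' or 'NP'", call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  tab <- table(condition)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("each condition (P and NP) needs at least 2 replicates",
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    condition = factor(condition, levels = c("P", "NP")),
    replicate = replicate
  )
  class(out) <- c("study_design", class(out))
  out
}

#' Read a study design from TSV
#'
#' Expects columns `sample_id`, `condition` (`P`|`NP`), `replicate`.
#'
#' @param path Path to a tab-separated design file.
#' @return A [study_design()] tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop("design file not found: ", path, call. = FALSE)
  }
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("design file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  study_design(d$sample_id, d$condition, as.integer(d$replicate))
}

# fixed metadata columns of the counts-table dialect, in order
.meta_cols <- c("accession", "gene", "species", "length_aa",
                "total_peptides", "unique_peptides")

#' Read a protein spectral-count table
#'
#' Reads the tab-separated protein-identification dialect: one row per
#' protein with the metadata columns `accession`, `gene`, `species`,
#' `length_aa`, `total_peptides`, `unique_peptides`, followed by one integer
#' spectral-count column per sample in `design`. The table is assumed to be
#' post search-engine FDR control; no identification scoring happens here.
#'
#' @param path Path to the TSV file.
#' @param design A [study_design()]; every `sample_id` must be a column.
#' @return A tibble of protein records (one row per protein) with the six
#'   metadata columns plus one integer count column per sample.
#' @export
read_counts_table <- function(path, design) {
  stopifnot(inherits(design, "study_design"))
  if (!file.exists(path)) {
    stop("counts file not found: ", path, call. = FALSE)
  }
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character())
  miss <- setdiff(c(.meta_cols, design$sample_id), names(d))
  if (length(miss)) {
    stop("counts table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, c(.meta_cols, design$sample_id)]
  if (nrow(d) == 0L) {
    warning("counts table has a header but no rows", call. = FALSE)
    return(.as_records(d, design$sample_id))
  }
  for (col in c("length_aa", "total_peptides", "unique_peptides",
                design$sample_id)) {
    v <- d[[col]]
    bad <- which(!grepl("^[0-9]+$", v))
    if (length(bad)) {
      stop(sprintf("column '%s': non-integer value '%s' at data row %d",
                   col, v[bad[1]], bad[1]), call. = FALSE)
    }
    d[[col]] <- as.integer(v)
  }
  .as_records(d, design$sample_id)
}

.as_records <- function(d, sample_ids) {
  d$length_aa <- as.integer(d$length_aa)
  d$total_peptides <- as.integer(d$total_peptides)
  d$unique_peptides <- as.integer(d$unique_peptides)
  for (s in sample_ids) d[[s]] <- as.integer(d[[s]])
  validate_records(d, sample_ids)
  tibble::as_tibble(d)
}

#' Validate protein records against the data-model invariants
#'
#' Checks `length_aa >= 1`, `unique_peptides <= total_peptides`,
#' non-negative counts, and presence of every design sample column.
#'
#' @param records Protein-record tibble as returned by [read_counts_table()].
#' @param sample_ids Character vector of expected count columns.
#' @return Invisibly, `records`; errors name the offending row.
#' @export
validate_records <- function(records, sample_ids) {
  miss <- setdiff(sample_ids, names(records))
  if (length(miss)) {
    stop("records lack sample column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))
  if (any(bad <- records$length_aa < 1L)) {
    stop("length_aa must be >= 1 (row ", which(bad)[1], ")", call. = FALSE)
  }
  if (any(bad <- records$unique_peptides > records$total_peptides)) {
    stop("unique_peptides exceeds total_peptides (row ", which(bad)[1], ")",
         call. = FALSE)
  }
  for (s in sample_ids) {
    if (any(bad <- records[[s]] < 0L)) {
      stop("negative spectral count in sample ", s, " (row ", which(bad)[1],
           ")", call. = FALSE)
    }
  }
  invisible(records)
}

#' Identification-level filter policy
#'
#' Defaults follow the acceptance rules of the identification workflow this
#' package ingests: at least two matched peptides per protein, at least one
#' unique peptide, and removal of cross-species duplicates arising from
#' searching a merged two-species (e.g. bovine + mouse) sequence library.
#'
#' @param min_total_peptides Minimum total matched peptides (default 2).
#' @param require_unique_peptide Drop proteins without a unique peptide
#'   (default `TRUE`).
#' @param deduplicate_cross_species Collapse records sharing a gene symbol
#'   across species to the best-supported one (default `TRUE`).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_total_peptides = 2L,
                          require_unique_peptide = TRUE,
                          deduplicate_cross_species = TRUE) {
  min_total_peptides <- as.integer(min_total_peptides)
  stopifnot(min_total_peptides >= 1L,
            is.logical(require_unique_peptide),
            is.logical(deduplicate_cross_species))
  structure(list(min_total_peptides = min_total_peptides,
                 require_unique_peptide = require_unique_peptide,
                 deduplicate_cross_species = deduplicate_cross_species),
            class = "filter_policy")
}

#' Apply identification-level filters
#'
#' Removes proteins with too few matched peptides, proteins without a unique
#' peptide, and cross-species duplicates. Deduplication groups surviving
#' records by gene symbol (case-insensitive; empty symbols are never
#' grouped) and keeps, within each group, the record with the highest summed
#' spectral count, breaking ties by lexicographically smallest accession.
#' Survivors keep their input order, and no counts are modified.
#'
#' @param records Protein-record tibble.
#' @param design A [study_design()] (identifies the count columns).
#' @param policy A [filter_policy()].
#' @return The filtered tibble, a subset of the input rows.
#' @export
apply_filters <- function(records, design, policy = filter_policy()) {
  stopifnot(inherits(design, "study_design"),
            inherits(policy, "filter_policy"))
  validate_records(records, design$sample_id)
  if (nrow(records) == 0L) return(records)

  keep <- records$total_peptides >= policy$min_total_peptides
  if (policy$require_unique_peptide) {
    keep <- keep & records$unique_peptides >= 1L
  }
  out <- records[keep, , drop = FALSE]
  if (policy$deduplicate_cross_species && nrow(out) > 1L) {
    counts <- as.matrix(out[, design$sample_id, drop = FALSE])
    total <- rowSums(counts)
    key <- toupper(trimws(out$gene))
    groupable <- !is.na(key) & nzchar(key)
    # within each gene group: max summed count, then smallest accession
    ord <- order(key, -total, out$accession)
    ranked <- out$accession[ord][!duplicated(key[ord])]
    winner <- !groupable | out$accession %in% ranked
    # a gene group can contain several rows tied on accession only if
    # accessions repeat; duplicated() on the ordered keys keeps exactly one
    out <- out[winner, , drop = FALSE]
  }
  out
}
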