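#' Run the full differential-interactor analysis
#'
#' Orchestrates the pipeline on a counts/design pair: identification-level
#' filtering, pseudocounted NSAF normalization, per-protein Welch
#' statistics, volcano classification, figure rendering, and a
#' machine-readable run summary. All artifacts are plain TSV/JSON (plus the
#' figure), so the run is scriptable and diffable.
#'
#' @param counts Path to a counts TSV, or a protein-record tibble.
#' @param design Path to a design TSV, or a [study_design()].
#' @param out_dir Output directory; created if needed.
#' @param policy A [filter_policy()].
#' @param params A [threshold_params()].
#' @param p_floor Lower p-value clamp (default `1e-300`).
#' @param normalization `"union"` or `"detected"`; see [compute_nsaf()].
#' @param log_base Log base of the volcano significance axis (default 10).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the in-memory results (`filtered`, `nsaf`,
#'   `diff`, `calls`, `summary`) and `paths` to the written artifacts:
#'   filtered-protein report, NSAF matrix, differential table, calls table,
#'   volcano figure (PNG + SVG), and `run_summary.json`.
#' @export
run_analyze <- function(counts, design, out_dir,
                        policy = filter_policy(),
                        params = threshold_params(),
                        p_floor = 1e-300,
                        normalization = c("union", "detected"),
                        log_base = 10,
                        quiet = FALSE) {
  normalization <- match.arg(normalization)
  say <- function(...) if (!quiet) message(...)

  if (!inherits(design, "study_design")) design <- read_design(design)
  if (!tibble::is_tibble(counts)) counts <- read_counts_table(counts, design)
  n_input <- nrow(counts)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage the peptide filters and the dedup separately so the summary can
  # report the count after each
  peptide_only <- filter_policy(policy$min_total_peptides,
                                policy$require_unique_peptide,
                                deduplicate_cross_species = FALSE)
  after_peptide <- apply_filters(counts, design, peptide_only)
  filtered <- apply_filters(after_peptide, design, policy)
  say("filters: ", n_input, " -> ", nrow(after_peptide),
      " (peptide evidence) -> ", nrow(filtered), " (deduplicated)")

  nsaf <- compute_nsaf(filtered, design, normalization = normalization)
  diff <- differential_table(nsaf, design, p_floor = p_floor,
                             log_base = log_base)
  calls <- classify_interactors(diff, params)
  tally <- table(calls$class_label)
  say("calls: ", tally[["P_SIGNIFICANT"]], " P-side, ",
      tally[["NP_SIGNIFICANT"]], " NP-side, ",
      tally[["NON_SIGNIFICANT"]], " non-significant")

  gene_map <- stats::setNames(filtered$gene, filtered$accession)
  paths <- c(
    filtered = file.path(out_dir, "filtered_proteins.tsv"),
    nsaf = file.path(out_dir, "nsaf_matrix.tsv"),
    differential = file.path(out_dir, "differential.tsv"),
    summary = file.path(out_dir, "run_summary.json")
  )
  readr::write_tsv(filtered, paths[["filtered"]])
  write_nsaf(nsaf, paths[["nsaf"]])
  write_differential(diff, paths[["differential"]], gene = gene_map)
  volcano_paths <- export_volcano(calls, params,
                                  file.path(out_dir, "volcano"))

  summary <- list(
    parameters = list(
      min_total_peptides = policy$min_total_peptides,
      require_unique_peptide = policy$require_unique_peptide,
      deduplicate_cross_species = policy$deduplicate_cross_species,
      threshold_n = params$n,
      threshold_m = params$m,
      p_floor = p_floor,
      normalization = normalization,
      log_base = log_base
    ),
    protein_counts = list(
      input = n_input,
      after_peptide_filters = nrow(after_peptide),
      after_deduplication = nrow(filtered)
    ),
    class_tallies = as.list(tally)
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(filtered = filtered, nsaf = nsaf, diff = diff,
                 calls = calls, summary = summary,
                 paths = c(paths, calls = volcano_paths[1],
                           figure_png = volcano_paths[2],
                           figure_svg = volcano_paths[3])))
}
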