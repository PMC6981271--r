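# shared fixture builders: tiny in-memory tables, no files on disk

toy_design <- function(reps = 3L) {
  study_design(
    sample_id = c(paste0("P", seq_len(reps)), paste0("NP", seq_len(reps))),
    condition = rep(c("P", "NP"), each = reps),
    replicate = rep(seq_len(reps), 2L)
  )
}

# records builder; counts is a matrix with one column per design sample
toy_records <- function(counts,
                        accession = sprintf("PROT%02d", seq_len(nrow(counts))),
                        gene = accession,
                        species = "BOVIN",
                        length_aa = rep(100L, nrow(counts)),
                        total_peptides = rep(5L, nrow(counts)),
                        unique_peptides = rep(2L, nrow(counts)),
                        design = toy_design()) {
  stopifnot(ncol(counts) == nrow(design))
  d <- tibble::tibble(accession = accession, gene = gene, species = species,
                      length_aa = as.integer(length_aa),
                      total_peptides = as.integer(total_peptides),
                      unique_peptides = as.integer(unique_peptides))
  for (j in seq_len(ncol(counts))) {
    d[[design$sample_id[j]]] <- as.integer(counts[, j])
  }
  d
}

write_counts_tsv <- function(records, path = withr::local_tempfile(
                               fileext = ".tsv", .local_envir = parent.frame())) {
  readr::write_tsv(records, path)
  path
}

# design with P/NP labels exchanged, sample ids unchanged
swap_design <- function(design) {
  study_design(design$sample_id,
               ifelse(design$condition == "P", "NP", "P"),
               design$replicate)
}
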