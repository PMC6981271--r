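#' Pseudocounted NSAF normalization
#'
#' Computes, for every protein k and sample s, the Normalized Spectral
#' Abundance Factor with a +1 pseudocount:
#'
#' \deqn{NSAF_{k,s} = \frac{(SpC_{k,s}+1)/L_k}{\sum_i (SpC_{i,s}+1)/L_i}}
#'
#' where \eqn{SpC} is the spectral count and \eqn{L_k} the protein length in
#' amino acids. The pseudocount keeps zero-count proteins at a finite,
#' strictly positive abundance, so log ratios between conditions remain
#' defined even when a protein is absent from one condition; the per-sample
#' denominator corrects for differences in sampling depth between runs.
#'
#' By default (`normalization = "union"`) the denominator runs over the full
#' filtered protein list with SpC = 0 imputed where a protein was not
#' observed, which makes NSAF values comparable across samples. With
#' `"detected"`, the denominator is restricted to proteins with SpC > 0 in
#' that sample (every protein still receives a value; column sums then
#' exceed 1 by the pseudocount mass of the undetected proteins).
#'
#' @param records Filtered protein-record tibble (see [apply_filters()]).
#' @param design A [study_design()].
#' @param normalization `"union"` (default) or `"detected"`; see Details.
#' @return A numeric matrix, proteins x samples, with `rownames` set to
#'   accessions and `colnames` to sample ids. Every entry is in (0, 1]; under
#'   `"union"` every column sums to 1.
#' @export
compute_nsaf <- function(records, design,
                         normalization = c("union", "detected")) {
  stopifnot(inherits(design, "study_design"))
  normalization <- match.arg(normalization)
  validate_records(records, design$sample_id)
  if (nrow(records) == 0L) {
    stop("no proteins after filtering", call. = FALSE)
  }
  spc <- as.matrix(records[, design$sample_id, drop = FALSE])
  storage.mode(spc) <- "double"
  num <- (spc + 1) / records$length_aa        # (SpC + 1) / L, recycled by row
  denom <- if (normalization == "union") {
    colSums(num)
  } else {
    colSums(num * (spc > 0))
  }
  if (any(denom <= 0)) {
    stop("a sample has no detected protein; cannot normalize per detected set",
         call. = FALSE)
  }
  nsaf <- sweep(num, 2L, denom, "/")
  dimnames(nsaf) <- list(records$accession, design$sample_id)
  nsaf
}

#' Per-condition mean NSAF
#'
#' Arithmetic mean of NSAF values over the biological replicates of each
#' condition, per protein.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param design A [study_design()]; each condition needs >= 2 samples.
#' @return A tibble with columns `accession`, `mean_P`, `mean_NP`; both
#'   means are strictly positive (pseudocount).
#' @export
condition_means <- function(nsaf, design) {
  stopifnot(inherits(design, "study_design"), is.matrix(nsaf))
  miss <- setdiff(design$sample_id, colnames(nsaf))
  if (length(miss)) {
    stop("NSAF matrix lacks sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p_cols <- design$sample_id[design$condition == "P"]
  np_cols <- design$sample_id[design$condition == "NP"]
  if (length(p_cols) < 2L || length(np_cols) < 2L) {
    stop("each condition needs at least 2 replicate samples", call. = FALSE)
  }
  tibble::tibble(
    accession = rownames(nsaf),
    mean_P = unname(rowMeans(nsaf[, p_cols, drop = FALSE])),
    mean_NP = unname(rowMeans(nsaf[, np_cols, drop = FALSE]))
  )
}

#' Write an NSAF matrix as TSV
#'
#' Full floating precision, one row per protein, one column per sample,
#' preceded by an `accession` column.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_nsaf <- function(nsaf, path) {
  d <- tibble::as_tibble(nsaf, rownames = "accession")
  for (s in colnames(nsaf)) d[[s]] <- formatC(d[[s]], format = "e", digits = 15)
  readr::write_tsv(d, path)
  invisible(path)
}
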