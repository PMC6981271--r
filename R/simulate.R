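#' Configuration for the pull-down spectral-count simulator
#'
#' Defaults emulate the statistical structure of a triplicate two-condition
#' pull-down identification list: hundreds of background proteins with a
#' shared, heavy-tailed abundance distribution; a minority of true
#' differential interactors enriched in one condition; protein lengths over
#' more than an order of magnitude; run-to-run variation in total sampling
#' depth; and overdispersed, frequently zero spectral counts.
#'
#' @param n_background Background (non-differential) proteins (default 500).
#' @param n_spiked_P,n_spiked_NP True interactors enriched in P / in NP
#'   (default 15 each).
#' @param fold_change True abundance fold change of spiked proteins in their
#'   enriched condition (default 8).
#' @param replicates_per_condition Biological replicates per condition,
#'   >= 2 (default 3).
#' @param depth_mean Expected total spectral counts per sample (default 3000).
#' @param depth_cv Coefficient of variation of per-sample depth (default
#'   0.15); depths are log-normal.
#' @param abundance_sigma Log-normal sigma of relative protein abundances
#'   (default 1.5).
#' @param length_range Protein length range in amino acids, drawn
#'   log-uniformly (default `c(80, 2000)`).
#' @param length_exponent Exponent linking length to peptide/spectrum yield:
#'   expected counts scale as `abundance * length^length_exponent`
#'   (default 0.7), so the 1/L NSAF correction is exercised.
#' @param count_dispersion Negative-binomial overdispersion `phi`
#'   (`var = mu + phi * mu^2`); 0 gives Poisson counts (default 0.2).
#' @param spike_quantile Abundance quantile floor for spiked proteins
#'   (default 0.75: spikes sit in the upper abundance quartile).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_background = 500L,
                              n_spiked_P = 15L,
                              n_spiked_NP = 15L,
                              fold_change = 8,
                              replicates_per_condition = 3L,
                              depth_mean = 3000,
                              depth_cv = 0.15,
                              abundance_sigma = 1.5,
                              length_range = c(80L, 2000L),
                              length_exponent = 0.7,
                              count_dispersion = 0.2,
                              spike_quantile = 0.75,
                              seed = 1L) {
  cfg <- list(n_background = as.integer(n_background),
              n_spiked_P = as.integer(n_spiked_P),
              n_spiked_NP = as.integer(n_spiked_NP),
              fold_change = fold_change,
              replicates_per_condition = as.integer(replicates_per_condition),
              depth_mean = depth_mean,
              depth_cv = depth_cv,
              abundance_sigma = abundance_sigma,
              length_range = as.integer(length_range),
              length_exponent = length_exponent,
              count_dispersion = count_dispersion,
              spike_quantile = spike_quantile,
              seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_background < 0L) bad <- c(bad, "n_background")
  if (cfg$n_spiked_P < 0L) bad <- c(bad, "n_spiked_P")
  if (cfg$n_spiked_NP < 0L) bad <- c(bad, "n_spiked_NP")
  if (!is.numeric(cfg$fold_change) || cfg$fold_change <= 0)
    bad <- c(bad, "fold_change")
  if (cfg$replicates_per_condition < 2L)
    bad <- c(bad, "replicates_per_condition")
  if (cfg$depth_mean <= 0) bad <- c(bad, "depth_mean")
  if (cfg$depth_cv < 0) bad <- c(bad, "depth_cv")
  if (cfg$abundance_sigma <= 0) bad <- c(bad, "abundance_sigma")
  if (length(cfg$length_range) != 2L || cfg$length_range[1] < 1L ||
      cfg$length_range[2] < cfg$length_range[1])
    bad <- c(bad, "length_range")
  if (cfg$count_dispersion < 0) bad <- c(bad, "count_dispersion")
  if (cfg$spike_quantile < 0 || cfg$spike_quantile >= 1)
    bad <- c(bad, "spike_quantile")
  if (length(bad)) {
    stop("invalid simulation_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# NB draw with var = mu + phi mu^2; phi = 0 falls back to Poisson
.rnbinom_phi <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a pull-down spectral-count experiment with known truth
#'
#' Per protein, a length is drawn log-uniformly and a relative abundance
#' log-normally; spiked proteins are drawn from the upper abundance quantile
#' (see `spike_quantile`) so triplicate power is non-trivial but achievable.
#' The expected count share of protein k in condition c is proportional to
#' `abundance_k * fc_kc * length_k^length_exponent`, where `fc_kc` is
#' `fold_change` for a spiked protein in its enriched condition and 1
#' otherwise, renormalized within the condition. Per sample, a total depth
#' is drawn log-normally (mean `depth_mean`, CV `depth_cv`) and counts are
#' negative-binomial around `depth * share`. Peptide-evidence columns are
#' filled so the default identification filters pass.
#'
#' @param config A [simulation_config()].
#' @return A list with `records` (protein tibble in the counts-table
#'   dialect), `design` (a [study_design()]) and `truth` (tibble:
#'   `accession`, `label` in BACKGROUND/SPIKED_P/SPIKED_NP,
#'   `true_abundance`, `true_fold_change`).
#' @export
simulate_pulldown <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_bg <- config$n_background
  n_sp <- config$n_spiked_P
  n_sn <- config$n_spiked_NP
  n <- n_bg + n_sp + n_sn
  if (n == 0L) stop("simulation has zero proteins", call. = FALSE)

  label <- rep(c("BACKGROUND", "SPIKED_P", "SPIKED_NP"), c(n_bg, n_sp, n_sn))
  accession <- sprintf("%s%04d_BOVIN",
                       c("BG", "SP", "SN")[match(label, c("BACKGROUND",
                                                          "SPIKED_P",
                                                          "SPIKED_NP"))],
                       c(seq_len(n_bg), seq_len(n_sp), seq_len(n_sn)))
  gene <- sub("_BOVIN$", "", accession)

  lr <- log(config$length_range)
  length_aa <- as.integer(round(exp(stats::runif(n, lr[1], lr[2]))))
  # background abundances span the whole log-normal; spikes are resampled
  # from its upper tail via the quantile transform
  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sigma)
  spiked <- label != "BACKGROUND"
  if (any(spiked)) {
    u <- stats::runif(sum(spiked), config$spike_quantile, 1)
    abundance[spiked] <- stats::qlnorm(u, meanlog = 0,
                                       sdlog = config$abundance_sigma)
  }

  reps <- config$replicates_per_condition
  design <- study_design(
    sample_id = c(paste0("P", seq_len(reps)), paste0("NP", seq_len(reps))),
    condition = rep(c("P", "NP"), each = reps),
    replicate = rep(seq_len(reps), 2L)
  )

  yield <- abundance * length_aa^config$length_exponent
  fc <- matrix(1, nrow = n, ncol = 2, dimnames = list(NULL, c("P", "NP")))
  fc[label == "SPIKED_P", "P"] <- config$fold_change
  fc[label == "SPIKED_NP", "NP"] <- config$fold_change
  share <- sweep(yield * fc, 2L, colSums(yield * fc), "/")

  cv2 <- config$depth_cv^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(config$depth_mean) - sdlog^2 / 2
  depth <- stats::rlnorm(nrow(design), meanlog, sdlog)

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(accession, design$sample_id))
  for (s in seq_len(nrow(design))) {
    mu <- depth[s] * share[, as.character(design$condition[s])]
    counts[, s] <- .rnbinom_phi(n, mu, config$count_dispersion)
  }

  max_spc <- apply(counts, 1L, max)
  total_peptides <- pmax(2L, as.integer(ceiling(max_spc / 3)))
  unique_peptides <- pmax(1L, total_peptides %/% 2L)

  records <- tibble::tibble(
    accession = accession,
    gene = gene,
    species = "BOVIN",
    length_aa = length_aa,
    total_peptides = total_peptides,
    unique_peptides = unique_peptides
  )
  for (s in design$sample_id) records[[s]] <- as.integer(counts[, s])

  truth <- tibble::tibble(
    accession = accession,
    label = factor(label, levels = c("BACKGROUND", "SPIKED_P", "SPIKED_NP")),
    true_abundance = abundance,
    true_fold_change = ifelse(spiked, config$fold_change, 1)
  )
  list(records = records, design = design, truth = truth)
}

#' Write a simulated experiment to TSV files
#'
#' Writes the counts table (the dialect [read_counts_table()] reads), the
#' design table, and the ground-truth table.
#'
#' @param sim Result of [simulate_pulldown()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, named character vector of the three paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, paste0(prefix, "_counts.tsv")),
             design = file.path(dir, paste0(prefix, "_design.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  readr::write_tsv(sim$records, paths["counts"])
  d <- sim$design
  d$condition <- as.character(d$condition)
  class(d) <- class(tibble::tibble())
  readr::write_tsv(d, paths["design"])
  tr <- sim$truth
  tr$label <- as.character(tr$label)
  readr::write_tsv(tr, paths["truth"])
  invisible(paths)
}

#' Score volcano calls against simulation ground truth
#'
#' Standard confusion-matrix summaries per side: SPIKED_P proteins are
#' judged against the P_SIGNIFICANT call, SPIKED_NP against NP_SIGNIFICANT.
#' The false-positive rate is the fraction of background proteins called
#' significant on that side.
#'
#' @param calls Tibble from [classify_interactors()].
#' @param truth Truth tibble from [simulate_pulldown()].
#' @return A tibble with one row per side (`P`, `NP`): `n_true`, `n_called`,
#'   `tp`, `recall`, `precision`, `fpr_background`. Recall and precision are
#'   `NA` when their denominator is empty.
#' @export
evaluate_calls <- function(calls, truth) {
  if (!setequal(calls$accession, truth$accession)) {
    stop("calls and truth cover different accession sets", call. = FALSE)
  }
  m <- dplyr::inner_join(calls, truth, by = "accession")
  n_bg <- sum(m$label == "BACKGROUND")
  side <- function(side_label, truth_label) {
    called <- m$class_label == side_label
    is_true <- m$label == truth_label
    tp <- sum(called & is_true)
    tibble::tibble(
      side = sub("_SIGNIFICANT$", "", side_label),
      n_true = sum(is_true),
      n_called = sum(called),
      tp = tp,
      recall = if (sum(is_true) > 0) tp / sum(is_true) else NA_real_,
      precision = if (sum(called) > 0) tp / sum(called) else NA_real_,
      fpr_background = if (n_bg > 0) {
        sum(called & m$label == "BACKGROUND") / n_bg
      } else NA_real_
    )
  }
  dplyr::bind_rows(side("P_SIGNIFICANT", "SPIKED_P"),
                   side("NP_SIGNIFICANT", "SPIKED_NP"))
}
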