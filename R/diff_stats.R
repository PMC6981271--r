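#' Welch's unequal-variance two-sample t-test
#'
#' Two-tailed t-test not assuming equal variances, with the
#' Welch--Satterthwaite approximation for the degrees of freedom:
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}, \qquad
#'       \nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'                  {\frac{(s_1^2/n_1)^2}{n_1-1} + \frac{(s_2^2/n_2)^2}{n_2-1}}}
#'
#' Degenerate inputs are resolved deterministically rather than rejected:
#' when both sample variances are zero and the means are equal, t = 0 and
#' p = 1; when both variances are zero but the means differ, the difference
#' is unambiguous at the observed resolution and p is set to `p_floor`
#' (with `t = +/-Inf` and `floored = TRUE`).
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @param p_floor Lower clamp for the p value in the zero-variance
#'   unequal-means case (default `1e-300`).
#' @return A list with `t_stat`, `df`, `p_value` and logical `floored`.
#' @export
welch_t_test <- function(group1, group2, p_floor = 1e-300) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) {
      return(list(t_stat = 0, df = n1 + n2 - 2, p_value = 1, floored = FALSE))
    }
    return(list(t_stat = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                p_value = p_floor, floored = TRUE))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t_stat = t_stat, df = df, p_value = p, floored = FALSE)
}

#' Per-protein differential statistics between conditions
#'
#' For every protein: condition means of NSAF, the log2 ratio
#' `a = log2(mean_P / mean_NP)`, a Welch two-tailed unequal-variance t-test
#' on the replicate NSAF values (untransformed, as produced by
#' [compute_nsaf()]), and the volcano significance coordinate
#' `b = -10 * log10(p)` (log base configurable). p values are clamped below
#' at `p_floor` before computing `b`, so `b` is always finite; clamped rows
#' carry `p_floored = TRUE`. No multiple-testing correction is applied:
#' interactor calling is controlled downstream by the threshold curve, not
#' by an FDR adjustment.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param design A [study_design()].
#' @param p_floor Lower clamp for p values, in (0, 1); default `1e-300`.
#' @param log_base Base of the logarithm in `b = -10 * log(p)`; default 10,
#'   the conventional volcano significance axis.
#' @return A tibble sorted by accession with columns `accession`, `mean_P`,
#'   `mean_NP`, `a` (log2 ratio), `t_stat`, `df`, `p_value`, `b`,
#'   `p_floored`.
#' @export
differential_table <- function(nsaf, design, p_floor = 1e-300,
                               log_base = 10) {
  stopifnot(is.numeric(p_floor), p_floor > 0, p_floor < 1, log_base > 1)
  means <- condition_means(nsaf, design)
  p_cols <- design$sample_id[design$condition == "P"]
  np_cols <- design$sample_id[design$condition == "NP"]
  tests <- lapply(seq_len(nrow(nsaf)), function(k) {
    welch_t_test(nsaf[k, p_cols], nsaf[k, np_cols], p_floor = p_floor)
  })
  p_raw <- vapply(tests, `[[`, numeric(1), "p_value")
  floored <- vapply(tests, `[[`, logical(1), "floored") | p_raw < p_floor
  p_clamped <- pmax(p_raw, p_floor)
  out <- tibble::tibble(
    accession = means$accession,
    mean_P = means$mean_P,
    mean_NP = means$mean_NP,
    # as a difference of logs: negation under a label swap is then exact
    a = log2(means$mean_P) - log2(means$mean_NP),
    t_stat = vapply(tests, `[[`, numeric(1), "t_stat"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_value = p_clamped,
    b = -10 * log(p_clamped, base = log_base),
    p_floored = floored
  )
  out[order(out$accession), , drop = FALSE]
}

#' Write a differential-results table as TSV
#'
#' @param diff Tibble from [differential_table()].
#' @param path Output path.
#' @param gene Optional named character vector mapping accession to gene
#'   symbol, written as a `gene` column when supplied.
#' @return Invisibly, `path`.
#' @export
write_differential <- function(diff, path, gene = NULL) {
  out <- diff
  if (!is.null(gene)) {
    out <- tibble::add_column(out, gene = unname(gene[out$accession]),
                              .after = "accession")
  }
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], formatC, format = "g", digits = 15)
  readr::write_tsv(out, path)
  invisible(path)
}
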