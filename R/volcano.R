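#' Volcano threshold-curve parameters
#'
#' The interactor-calling boundary on the volcano plane is the hyperbola
#' `f(x) = 1/(x^2 - n) + m` together with the fold-change gate `|a| > sqrt(n)`.
#' `n` controls the log2-ratio axis (the curve's vertical asymptotes sit at
#' `x = +/-sqrt(n)`), `m` the significance axis (the curve's horizontal
#' asymptote). Defaults are n = 1.35 and m = 5, i.e. a fold-change gate at
#' `|a| > 1.162` and a significance asymptote at p ~ 0.316 on the
#' `-10*log10(p)` scale, a permissive significance floor tightened near the
#' fold-change gate by the hyperbola.
#'
#' @param n Ratio-axis parameter, > 0 (default 1.35).
#' @param m Significance-axis parameter, >= 0 (default 5).
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(n = 1.35, m = 5) {
  stopifnot(is.numeric(n), n > 0, is.numeric(m), m >= 0)
  structure(list(n = n, m = m), class = "threshold_params")
}

#' Evaluate the hyperbolic threshold curve
#'
#' `f(x) = 1/(x^2 - n) + m`, defined only outside the fold-change gate
#' (`x^2 > n`). Inside the gate the curve has its pole/negative branch and no
#' point can pass; `NA` is returned there as a sentinel.
#'
#' @param x Numeric vector of log2-ratio coordinates.
#' @param params A [threshold_params()].
#' @return Numeric vector: `1/(x^2 - n) + m` where `x^2 > n`, `NA` elsewhere.
#' @export
threshold_curve <- function(x, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  out <- rep(NA_real_, length(x))
  ok <- x^2 > params$n
  out[ok] <- 1 / (x[ok]^2 - params$n) + params$m
  out
}

#' Classify proteins on the volcano plane
#'
#' A protein is called a P-side interactor iff `a > sqrt(n)` and
#' `b > f(a)`; an NP-side interactor iff `a < -sqrt(n)` and `b > f(a)`;
#' otherwise non-significant. All inequalities are strict: boundary points
#' (including `|a| = sqrt(n)`, where the curve is undefined) are
#' non-significant.
#'
#' @param results Tibble from [differential_table()] (needs columns
#'   `accession`, `a`, `b`).
#' @param params A [threshold_params()].
#' @return A tibble with columns `accession`, `a`, `b`, `class_label`
#'   (factor: `P_SIGNIFICANT`, `NP_SIGNIFICANT`, `NON_SIGNIFICANT`).
#' @export
classify_interactors <- function(results, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"),
            all(c("accession", "a", "b") %in% names(results)))
  a <- results$a
  b <- results$b
  f <- threshold_curve(a, params)
  passes <- !is.na(f) & b > f
  root_n <- sqrt(params$n)
  label <- rep("NON_SIGNIFICANT", length(a))
  label[passes & a > root_n] <- "P_SIGNIFICANT"
  label[passes & a < -root_n] <- "NP_SIGNIFICANT"
  tibble::tibble(
    accession = results$accession,
    a = a,
    b = b,
    class_label = factor(label, levels = c("P_SIGNIFICANT", "NP_SIGNIFICANT",
                                           "NON_SIGNIFICANT"))
  )
}

#' Write volcano calls and render the volcano figure
#'
#' Writes (i) a TSV of calls (`accession`, `a`, `b`, `class_label`) and
#' (ii) the volcano figure with both threshold-curve branches, to PNG and
#' SVG. Curve branches are sampled on `|x| in (sqrt(n) + eps, x_max]` with
#' `eps` chosen so the drawn curve tops out at the plot's y ceiling — a
#' purely cosmetic clip, since the curve diverges at the gate.
#'
#' @param calls Tibble from [classify_interactors()].
#' @param params The [threshold_params()] used for the calls.
#' @param path_prefix Output path prefix; writes `<prefix>_calls.tsv`,
#'   `<prefix>.png`, `<prefix>.svg`.
#' @return Invisibly, a character vector of the written paths.
#' @export
export_volcano <- function(calls, params = threshold_params(),
                           path_prefix = "volcano") {
  tsv <- paste0(path_prefix, "_calls.tsv")
  readr::write_tsv(calls, tsv)

  root_n <- sqrt(params$n)
  x_max <- max(3 * root_n, calls$a, -calls$a, na.rm = TRUE) * 1.05
  if (!is.finite(x_max)) x_max <- 3 * root_n
  y_max <- max(params$m * 4, calls$b, na.rm = TRUE) * 1.05
  if (!is.finite(y_max)) y_max <- params$m * 4
  # eps solves f(root_n + eps) = y_max so the drawn branch meets the ceiling
  x_at_ceiling <- sqrt(params$n + 1 / (y_max - params$m))
  grid <- seq(x_at_ceiling, x_max, length.out = 400)
  curve_df <- rbind(
    data.frame(x = grid, y = threshold_curve(grid, params), branch = "pos"),
    data.frame(x = -grid, y = threshold_curve(-grid, params), branch = "neg")
  )

  pal <- c(P_SIGNIFICANT = "#c0392b", NP_SIGNIFICANT = "#2874a6",
           NON_SIGNIFICANT = "grey55")
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = calls,
      ggplot2::aes(x = .data$a, y = .data$b, colour = .data$class_label),
      size = 1.4, alpha = 0.8
    ) +
    ggplot2::geom_line(
      data = curve_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$branch),
      linetype = "dashed", linewidth = 0.4
    ) +
    ggplot2::scale_colour_manual(values = pal, limits = names(pal),
                                 drop = FALSE, name = NULL) +
    ggplot2::coord_cartesian(xlim = c(-x_max, x_max), ylim = c(0, y_max)) +
    ggplot2::labs(
      x = expression(log[2] * "(Mean NSAF"[P] * " / Mean NSAF"[NP] * ")"),
      y = expression(-10 %.% log[10] * "(p value)")
    ) +
    ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(legend.position = "bottom")

  png_path <- paste0(path_prefix, ".png")
  svg_path <- paste0(path_prefix, ".svg")
  ggplot2::ggsave(png_path, p, width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(svg_path, p, width = 6, height = 5,
                  device = grDevices::svg)
  invisible(c(tsv, png_path, svg_path))
}
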