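#' Export PheWAS plot data
#'
#' Turns an annotated result table into plot-ready rows: phenotypes ordered
#' by category then phecode, one x-position per phenotype (shared by the
#' unadjusted and BMI-adjusted rows of the same phenotype), `-log10(p)`,
#' effect direction, and the adjustment flag that the conventional
#' triangle/dot distinction encodes. Threshold lines travel along as the
#' `"thresholds"` attribute.
#'
#' @param results An annotated scan or meta tibble (needs `phecode`,
#'   `category`, `p`, `beta`, `bmi_adjusted`). Concatenate the unadjusted and
#'   adjusted tables to plot both.
#' @param thresholds Optional `threshold_set` carried into the attribute.
#' @return Tibble `phecode, description, category, x, neg_log10_p, direction,
#'   bmi_adjusted` plus pass flags when present.
#' @export
export_plot_data <- function(results, thresholds = NULL) {
  results <- tibble::as_tibble(results)
  if (!"bmi_adjusted" %in% names(results))
    results$bmi_adjusted <- FALSE
  xs <- dplyr::distinct(results, .data$category, .data$phecode) |>
    dplyr::arrange(.data$category, .data$phecode) |>
    dplyr::mutate(x = dplyr::row_number())
  out <- dplyr::inner_join(results, xs, by = c("category", "phecode")) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p),
                  direction = sign(.data$beta)) |>
    dplyr::arrange(.data$x, .data$bmi_adjusted)
  keep <- intersect(c("snp_id", "phecode", "description", "category", "x",
                      "neg_log10_p", "direction", "bmi_adjusted", "p", "or",
                      "pass_bonferroni", "pass_bh", "pass_simplem"),
                    names(out))
  out <- out[, keep]
  attr(out, "thresholds") <- thresholds
  out
}

#' Phenome-wide association plot
#'
#' Points are phenotypes at their category-ordered x-position against
#' `-log10(p)`, colored by phenotype category; when both adjustments are
#' present, shape distinguishes BMI-unadjusted (triangles) from adjusted
#' (dots) at a shared x-position. Horizontal lines mark the Bonferroni and
#' Benjamini-Hochberg thresholds when supplied.
#'
#' @param plot_data Output of [export_plot_data()], or an annotated result
#'   table (converted on the fly).
#' @param thresholds Optional `threshold_set`; defaults to the attribute left
#'   by [export_plot_data()].
#' @return A ggplot object.
#' @export
plot_phewas <- function(plot_data, thresholds = attr(plot_data, "thresholds")) {
  if (!"x" %in% names(plot_data))
    plot_data <- export_plot_data(plot_data, thresholds)
  g <- ggplot2::ggplot(plot_data,
                       ggplot2::aes(x = .data$x, y = .data$neg_log10_p,
                                    colour = .data$category,
                                    shape = .data$bmi_adjusted)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 17, `TRUE` = 16),
                                labels = c(`FALSE` = "unadjusted",
                                           `TRUE` = "BMI-adjusted"),
                                name = NULL) +
    ggplot2::labs(x = "phenotype (grouped by category)",
                  y = expression(-log[10](p)), colour = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(thresholds)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(thresholds$bonferroni_p),
                                 colour = "deeppink", linetype = 2)
    if (thresholds$bh_p > 0)
      g <- g + ggplot2::geom_hline(yintercept = -log10(thresholds$bh_p),
                                   colour = "blue", linetype = 3)
  }
  g
}

#' @rdname plot_phewas
#' @param object A `phewas_meta` or `phewas_scan` table.
#' @param ... Passed to [plot_phewas()].
#' @export
autoplot.phewas_meta <- function(object, ...) plot_phewas(object, ...)

#' @rdname plot_phewas
#' @export
autoplot.phewas_scan <- function(object, ...) plot_phewas(object, ...)
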