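# ggplot2 visualisations for the package's result types.

#' Plot a TSS-anchored meta-profile
#'
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @return A ggplot: value against gene-oriented distance from the TSS, with
#'   the TSS marked.
#' @export
autoplot.meta_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from TSS (bp)",
                  y = attr(object, "statistic"),
                  title = sprintf("%s (%s, %d genes)", attr(object, "statistic"),
                                  attr(object, "normalization"),
                                  attr(object, "n_genes"))) +
    ggplot2::theme_minimal()
}

#' Plot classified transcription-rate changes
#'
#' @param object A `gro_changes` object.
#' @param ... Unused.
#' @return A ggplot of ranked mutant/control ratios coloured by status, with
#'   the classification thresholds drawn.
#' @export
autoplot.gro_changes <- function(object, ...) {
  df <- tidy(object) %>%
    filter(!is.na(.data$ratio)) %>%
    arrange(.data$ratio) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ratio,
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = c(attr(object, "down_threshold"),
                                       attr(object, "up_threshold")),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Genes ranked by ratio", y = "mutant/control ratio") +
    ggplot2::theme_minimal()
}

#' Plot a TFBS bin matrix as a heat map
#'
#' @param object A `tfbs_matrix`.
#' @param ... Unused.
#' @return A ggplot heat map, factors by TSS-relative bins.
#' @export
autoplot.tfbs_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$factor,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Distance from TSS (bp)", y = NULL,
                  fill = attr(object, "normalization")) +
    ggplot2::theme_minimal()
}

#' Bar plot of enrichment ratios with significance stars
#'
#' Works on any tibble with `ratio`, `p_value` and a category column, e.g.
#' the outputs of [remodeler_enrichment()] or the class-enrichment table of
#' [run_pipeline()].
#'
#' @param enrichment Tibble with at least `ratio` and `p_value` columns.
#' @param x Name of the category column (default `"remodeler"`).
#' @param facet Optional name of a faceting column (e.g. `"set"`).
#' @param alpha Star threshold on `p_value` (default 0.001).
#' @return A ggplot bar chart of ratios around the genome-average line at 1;
#'   significant bars are starred.
#' @export
plot_enrichment <- function(enrichment, x = "remodeler", facet = "set",
                            alpha = 0.001) {
  df <- mutate(as_tibble(enrichment),
               star = ifelse(.data$p_value < alpha, "*", ""))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), vjust = -0.2) +
    ggplot2::labs(y = "observed / expected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(facet) && facet %in% names(df)) {
    p <- p + ggplot2::facet_wrap(facet)
  }
  p
}
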