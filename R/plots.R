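# ggplot2 views of the pipeline's result objects.

#' @export
autoplot.spectrum_pca <- function(object, x = "PC1", y = "PC2", ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data[[x]], .data[[y]], colour = .data$condition)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf(
        "%s (%.0f%%)", x,
        100 * object$explained_variance$fraction[
          object$explained_variance$component == x
        ]
      ),
      y = sprintf(
        "%s (%.0f%%)", y,
        100 * object$explained_variance$fraction[
          object$explained_variance$component == y
        ]
      ),
      colour = "condition",
      title = "Pluripotent-state spectrum"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectrum_de <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(base_mean = (.data$mean_a + .data$mean_b) / 2)
  ggplot2::ggplot(
    d, ggplot2::aes(.data$base_mean, .data$log2fc,
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::facet_wrap(~ paste(condition_a, "vs", condition_b)) +
    ggplot2::labs(
      x = "mean normalized count", y = "log2 fold change",
      title = "Pairwise differential expression"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectrum_correlation <- function(object, ...) {
  long <- object$correlation %>%
    tidyr::pivot_longer(-"sample_id",
      names_to = "sample_2", values_to = "r"
    ) %>%
    mutate(
      sample_id = factor(.data$sample_id, levels = object$dendrogram_order),
      sample_2 = factor(.data$sample_2, levels = object$dendrogram_order)
    )
  ggplot2::ggplot(
    long, ggplot2::aes(.data$sample_id, .data$sample_2, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick", midpoint = 0.5
    ) +
    ggplot2::labs(
      x = NULL, y = NULL, title = "Global expression correlation"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' Global methylation gradient across conditions
#'
#' @param global_meth Tibble with `sample_id`, `condition`, `global_level`
#'   (the pipeline's `global_methylation.tsv`).
#' @param condition_order Optional condition ordering (e.g. the spectrum
#'   order).
#' @return A ggplot.
#' @export
plot_methylation_spectrum <- function(global_meth, condition_order = NULL) {
  if (!is.null(condition_order)) {
    global_meth <- global_meth %>%
      mutate(condition = factor(.data$condition, levels = condition_order))
  }
  ggplot2::ggplot(
    global_meth,
    ggplot2::aes(.data$condition, .data$global_level)
  ) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "weighted 5-mC level",
      title = "Global DNA methylation across the spectrum"
    ) +
    ggplot2::theme_minimal()
}

#' TE class composition of significant families
#'
#' @param breakdown Output of [class_breakdown()].
#' @return A ggplot.
#' @export
plot_class_breakdown <- function(breakdown) {
  ggplot2::ggplot(
    breakdown,
    ggplot2::aes(.data$te_class, .data$n_significant, fill = .data$te_class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "TE class", y = "differentially active families",
      title = "Class breakdown of TE activation"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
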