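#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of the permuted covariance-ratio null
#'
#' @param object A [cr_test()] result.
#' @param ... Unused.
#' @return A ggplot: null CR distribution with the observed value marked.
#' @export
autoplot.cr_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$cr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red", linewidth = 1) +
    ggplot2::labs(
      x = "covariance ratio (permuted landmark assignments)", y = "count",
      title = sprintf("Modularity test: CR = %.3f, p = %.3g", object$observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of the first-pair PLS block scores
#'
#' @param object A [phylo_pls()] result.
#' @param ... Unused.
#' @export
autoplot.phylo_pls <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$block1, y = .data$block2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.5) +
    ggplot2::labs(
      x = "block 1 PLS scores", y = "block 2 PLS scores",
      title = sprintf("Phylogenetic PLS: r = %.3f, p = %.3g", object$r_pls, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of the simulated equal-rate null ratios
#'
#' @param object A [compare_module_rates()] result.
#' @param ... Unused.
#' @export
autoplot.rate_test <- function(object, ...) {
  df <- tibble::tibble(ratio = object$null_ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$ratio, color = "red", linewidth = 1) +
    ggplot2::labs(
      x = sprintf("%s / %s rate ratio under equal-rate null", object$modules[1], object$modules[2]),
      y = "count",
      title = sprintf("Rate ratio = %.2f, p = %.3g", object$ratio, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Phylomorphospace plot
#'
#' Tips at their PC1/PC2 scores, internal nodes at BM ancestral states,
#' branches as segments; tips colored by group when provided.
#'
#' @param object A [phylomorphospace()] result.
#' @param ... Unused.
#' @export
autoplot.phylomorphospace <- function(object, ...) {
  tips <- object$nodes[object$nodes$type == "tip", ]
  ints <- object$nodes[object$nodes$type == "internal", ]
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = object$edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = ints, ggplot2::aes(x = .data$PC1, y = .data$PC2),
                        size = 1, color = "grey40")
  if (all(is.na(tips$group))) {
    gg <- gg + ggplot2::geom_point(data = tips, ggplot2::aes(x = .data$PC1, y = .data$PC2), size = 2)
  } else {
    gg <- gg + ggplot2::geom_point(
      data = tips, ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data$group), size = 2)
  }
  gg + ggplot2::labs(x = "PC1", y = "PC2", title = "Phylomorphospace") +
    ggplot2::theme_minimal()
}

#' Distribution of skewer indices
#'
#' @param object A [skewer_indices()] result.
#' @param ... Unused.
#' @export
autoplot.skewer_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$raw, -"skewer",
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(title = sprintf("Random-skewers indices: %s", object$module),
                  x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
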