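# ggplot2 views of the main result types.

#' @method autoplot admixture_ensemble
#' @export
autoplot.admixture_ensemble <- function(object, K = NULL, ...) {
  if (is.null(K)) K <- utils::tail(object$K_range, 1)
  td <- tidy(object, K = K)
  ord <- td |>
    dplyr::filter(.data$cluster == "K1") |>
    dplyr::arrange(dplyr::desc(.data$mean)) |>
    dplyr::pull(.data$specimen)
  ggplot2::ggplot(td, ggplot2::aes(
    x = factor(.data$specimen, levels = ord),
    y = .data$mean, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "mean ancestry",
                  title = paste0("Admixture proportions, K = ", K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Cross-entropy curve across K
#'
#' @param ensemble An `admixture_ensemble`.
#' @return A ggplot.
#' @export
plot_cross_entropy <- function(ensemble) {
  g <- glance(ensemble)
  ggplot2::ggplot(g, ggplot2::aes(.data$K, .data$mean_cross_entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_cross_entropy - .data$sd_cross_entropy,
      ymax = .data$mean_cross_entropy + .data$sd_cross_entropy)) +
    ggplot2::scale_x_continuous(breaks = g$K) +
    ggplot2::labs(y = "masked cross-entropy",
                  title = "Cross-entropy model choice") +
    ggplot2::theme_minimal()
}

#' @method autoplot maldi_clustering
#' @export
autoplot.maldi_clustering <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(.data$k, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = object$bic$k) +
    ggplot2::labs(y = "BIC", title = paste0("k-means BIC (optimum k = ",
                                            object$k_opt, ")")) +
    ggplot2::theme_minimal()
}

#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, n = 20, ...) {
  top <- utils::head(object$importance, n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(sprintf("%.0f", .data$bin), .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "peak (m/z)", y = "mean decrease accuracy",
                  title = "Random-forest peak importance") +
    ggplot2::theme_minimal()
}

#' @method autoplot intensity_matrix
#' @export
autoplot.intensity_matrix <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = factor(sprintf("%.0f", .data$bin)),
    y = .data$specimen, fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "peak (m/z)", y = NULL, fill = "intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5))
}

#' Plot a haplotype network
#'
#' Base-graphics plot of the unit-step network; observed haplotypes are
#' drawn with area proportional to multiplicity, inferred intermediates
#' as small filled points.
#'
#' @param x A `haplotype_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- x$graph
  inferred <- igraph::V(g)$inferred
  mult <- igraph::V(g)$multiplicity
  igraph::plot.igraph(
    g,
    vertex.size = ifelse(inferred, 2, 5 + 3 * sqrt(mult)),
    vertex.color = ifelse(inferred, "black", "steelblue"),
    vertex.label = ifelse(inferred, NA, igraph::V(g)$name),
    ...)
  invisible(x)
}
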