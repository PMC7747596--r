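# ggplot2 views of the main result types.

#' Scores plot of a PLS-DA fit
#'
#' @param object A `plsda_fit`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot: per-sample scores on the two components, colored by
#'   class.
#' @method autoplot plsda_fit
#' @export
autoplot.plsda_fit <- function(object, components = c(1, 2), ...) {
  stopifnot(max(components) <= object$n_components)
  scores <- tidy(object, "scores")
  xs <- paste0("comp", components[1])
  ys <- paste0("comp", components[2])
  ggplot2::ggplot(scores, ggplot2::aes(
    .data[[xs]], .data[[ys]], colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = paste("Component", components[1]),
                  y = paste("Component", components[2]),
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}

#' VIP bar plot
#'
#' @param model A `plsda_fit`.
#' @param k Number of top analytes to show (default 15).
#' @return A ggplot of the top-k VIP scores.
#' @export
plot_vip <- function(model, k = 15) {
  top <- rank_top_k(model, k)
  ggplot2::ggplot(top, ggplot2::aes(
    .data$vip, stats::reorder(.data$analyte, .data$vip))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Variable importance in projection", y = NULL) +
    ggplot2::theme_minimal()
}

#' Class-composition bar plot
#'
#' @param composition Output of [class_composition()] with genotype and
#'   treatment grouping.
#' @return A ggplot of class shares per genotype x treatment.
#' @export
plot_class_composition <- function(composition) {
  ggplot2::ggplot(composition, ggplot2::aes(
    .data$genotype, .data$share, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(y = "Percent of total signal", x = NULL,
                  fill = "Class") +
    ggplot2::theme_minimal()
}

#' Dendrogram view of a co-occurrence result
#'
#' @param object A `cooccurrence_result`.
#' @param ... Unused.
#' @return A ggplot of the single-linkage merge profile (merge similarity by
#'   step), with the group threshold marked.
#' @method autoplot cooccurrence_result
#' @export
autoplot.cooccurrence_result <- function(object, ...) {
  merges <- object$tree$merges
  ggplot2::ggplot(merges, ggplot2::aes(.data$step, .data$rho)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "Merge step", y = "Linkage Spearman rho") +
    ggplot2::theme_minimal()
}
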