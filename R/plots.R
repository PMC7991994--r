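# ggplot2 diagnostics: feature distributions by group, the PCA biplot and
# the evaluation grid.

#' Box plots of the 15 features by group
#'
#' @param table Feature table from [build_feature_table()].
#' @return A ggplot.
#' @export
plot_feature_distributions <- function(table) {
  long <- table |>
    tidyr::pivot_longer(all_of(phonatory_feature_names),
                        names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$group, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~ .data$feature, scales = "free_y") +
    labs(x = NULL, y = NULL, fill = "Group") +
    theme_minimal()
}

#' @describeIn pca_svd Biplot of the first two components: scores coloured
#'   by group with feature loading vectors overlaid.
#' @param object A `phonatory_pca`.
#' @exportS3Method ggplot2::autoplot
autoplot.phonatory_pca <- function(object, ...) {
  bp <- biplot_export(object)
  arrow_scale <- 0.8 * max(abs(c(bp$scores$Dim1, bp$scores$Dim2))) /
    max(abs(c(bp$loadings$Dim1, bp$loadings$Dim2)))
  lab <- sprintf("Dim%d (%.1f%%)", 1:2, 100 * bp$variance_share)
  p <- ggplot(bp$scores, aes(x = .data$Dim1, y = .data$Dim2))
  if ("group" %in% names(bp$scores)) {
    p <- p + geom_point(aes(colour = .data$group), alpha = 0.7)
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p +
    geom_segment(data = bp$loadings,
                 aes(x = 0, y = 0, xend = .data$Dim1 * arrow_scale,
                     yend = .data$Dim2 * arrow_scale),
                 arrow = grid::arrow(length = grid::unit(2, "mm")),
                 colour = "grey30") +
    geom_text(data = bp$loadings,
              aes(x = .data$Dim1 * arrow_scale * 1.08,
                  y = .data$Dim2 * arrow_scale * 1.08,
                  label = .data$feature),
              size = 2.5, colour = "grey30") +
    labs(x = lab[1], y = lab[2], colour = "Group") +
    theme_minimal()
}

#' @describeIn repeated_kfold_evaluate Bar chart of aggregated accuracy per
#'   model and comparison, faceted by threshold.
#' @param object A `phonatory_evaluation`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.phonatory_evaluation <- function(object, ...) {
  s <- summarize_evaluation(object)
  if (!"comparison" %in% names(s)) s$comparison <- "all"
  ggplot(s, aes(x = .data$comparison, y = .data$accuracy,
                fill = .data$model)) +
    geom_col(position = "dodge") +
    facet_wrap(~ .data$threshold,
               labeller = label_both) +
    labs(x = NULL, y = "Accuracy (%)", fill = "Model") +
    theme_minimal()
}
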