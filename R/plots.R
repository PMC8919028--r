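# ggplot2 visualizations for the main result types.

#' @describeIn pcoa_ord Ordination scatter of the first two axes; pass a
#'   data frame via `colour_by` (columns `sample_id` + one annotation) to
#'   color points.
#' @param object the object to plot.
#' @param colour_by optional two-column data frame (`sample_id`, annotation).
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ord <- function(object, colour_by = NULL, ...) {
  dat <- object$scores
  mapping <- ggplot2::aes(x = .data$Axis1, y = .data$Axis2)
  if (!is.null(colour_by)) {
    ann <- names(colour_by)[2]
    dat <- left_join(dat, colour_by, by = "sample_id")
    mapping <- ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                            colour = .data[[ann]])
  }
  ggplot2::ggplot(dat, mapping) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_explained[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_transitions Heatmap of transition probabilities
#'   (rows = origin state, columns = destination).
#' @param object the object to plot.
#' @exportS3Method ggplot2::autoplot
autoplot.transition_model <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$to, y = .data$from,
                                 fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = paste("State transitions:", object$body_site),
                  x = "to state", y = "from state", fill = "P") +
    ggplot2::theme_minimal()
}

#' @describeIn partition_processes Stacked bars of process fractions per
#'   group.
#' @param object the object to plot.
#' @exportS3Method ggplot2::autoplot
autoplot.process_partition <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of pairs",
                  fill = "assembly process") +
    ggplot2::theme_minimal()
}

#' Heatmap of state-by-site representation
#'
#' Tile plot of [site_representation()] percentages with deviations from the
#' uniform share annotated.
#'
#' @param representation output of [site_representation()].
#' @return A ggplot.
#' @export
plot_site_representation <- function(representation) {
  ggplot2::ggplot(representation,
                  ggplot2::aes(x = .data$body_site, y = .data$state,
                               fill = .data$deviation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "deviation\nfrom uniform") +
    ggplot2::theme_minimal()
}

#' @describeIn build_network Network edge map: retained edges as tiles of
#'   signed Spearman rho over the ASV pair grid.
#' @param object the object to plot.
#' @exportS3Method ggplot2::autoplot
autoplot.cooccurrence_network <- function(object, ...) {
  kept <- filter(object$edges, .data$kept)
  ggplot2::ggplot(kept, ggplot2::aes(x = .data$asv_a, y = .data$asv_b,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(title = if (!is.na(object$group)) {
      paste("Co-occurrence network:", object$group)
    }, x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
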