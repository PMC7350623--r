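# ggplot2 visualizations for the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_abline geom_hline labs scale_fill_gradient2 theme_minimal
#'   scale_x_continuous scale_y_continuous facet_wrap
#' @export
ggplot2::autoplot

#' Volcano-style plot of a marker-discovery result
#'
#' Mean log2 fold change against -log10 mean p-value over all tested probes;
#' selected candidates are highlighted.
#'
#' @param object a `marker_discovery` object from [discover_markers()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot marker_discovery
#' @export
autoplot.marker_discovery <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(mean_log2fc, -log10(pmax(mean_p, 1e-300)),
                colour = .data$selected)) +
    geom_point(alpha = 0.6, size = 1) +
    labs(
      x = "mean log2 fold change (target - rest)",
      y = "-log10 mean p-value",
      colour = "selected",
      title = paste0("Marker candidates: ", attr(object, "stats")$target_class[1])
    ) +
    theme_minimal()
}

#' Signature-score heatmap of group calls
#'
#' Per-sample, per-entity z-scores as a tile map, with called samples marked.
#'
#' @param object a `group_calls` object from [call_groups()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot group_calls
#' @export
autoplot.group_calls <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(sample_id, entity, fill = z)) +
    geom_tile() +
    geom_point(
      data = dplyr::filter(d, .data$called_entity == .data$entity),
      shape = 8, size = 2
    ) +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z",
         title = "Entity signature z-scores (* = called)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' ROC curve of a single probe
#' @param object a `probe_roc` object from [probe_roc()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot probe_roc
#' @export
autoplot.probe_roc <- function(object, ...) {
  ggplot(object$points, aes(fpr, tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_continuous(limits = c(0, 1)) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s (AUC = %.3f)", object$probe, object$auc)
    ) +
    theme_minimal()
}

#' Per-entity AUC dot plot
#' @param object an `auc_table` from [auc_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot auc_table
#' @export
autoplot.auc_table <- function(object, ...) {
  ggplot(as_tibble(object), aes(auc, probe)) +
    geom_point() +
    facet_wrap(~entity, scales = "free_y") +
    scale_x_continuous(limits = c(0, 1)) +
    labs(x = "AUC (one-vs-rest)", y = NULL) +
    theme_minimal()
}
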