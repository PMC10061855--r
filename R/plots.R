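#' Bar-and-error plot of a water-status index
#'
#' Group means with SD error bars per stage, faceted by ecotype, with the
#' compact significance letters above the bars.
#'
#' @param object A `dm_physio_summary` from [summarize_physiology()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dm_physio_summary
#' @export
autoplot.dm_physio_summary <- function(object, ...) {
  df <- as_tibble(unclass_first(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mean,
                                   fill = .data$ecotype)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + .data$sd, label = .data$letters),
      position = ggplot2::position_dodge(0.9), vjust = -0.4, size = 3,
      na.rm = TRUE) +
    ggplot2::labs(x = "stage", y = attr(object, "index"), fill = "ecotype") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression contrast
#'
#' @param object A `dm_contrast` from [nb_test()].
#' @param ... Unused.
#' @return A ggplot object (log2 fold change vs -log10 adjusted p, coloured
#'   by call, with the thresholds drawn).
#' @method autoplot dm_contrast
#' @export
autoplot.dm_contrast <- function(object, ...) {
  df <- filter(as_tibble(unclass_first(object)), !is.na(.data$padj))
  alpha <- attr(object, "alpha")
  lfc <- attr(object, "lfc_min")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#D55E00", down = "#0072B2", ns = "grey70")) +
    ggplot2::labs(x = sprintf("log2 FC (%s vs %s)", object$comparison[1],
                              object$baseline[1]),
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Category-count bar chart for classified genes
#'
#' @param records A `dm_dmg` tibble from [classify_all()].
#' @param drop_none Hide the `none` category (default TRUE).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(records, drop_none = TRUE) {
  df <- count(as_tibble(records), .data$category)
  if (drop_none) df <- filter(df, .data$category != "none")
  df$category <- factor(df$category, levels = DM_CATEGORIES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#E8A33D") +
    ggplot2::labs(x = "trajectory category", y = "genes") +
    ggplot2::theme_minimal()
}

#' Signed TF-target correlation heatmap
#'
#' Tile map of retained co-expression edges: regulators on one axis, target
#' genes on the other, fill encoding the signed Pearson r (positive and
#' negative correlations in contrasting hues), the display behind switch
#' modules.
#'
#' @param edges A `dm_edges` tibble (usually after [filter_edges()]).
#' @return A ggplot object.
#' @export
plot_switch_heatmap <- function(edges) {
  df <- as_tibble(edges)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$tf,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#0072B2", mid = "white",
                                  high = "#E8A33D", limits = c(-1, 1)) +
    ggplot2::labs(x = "functional DMG", y = "regulator", fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Hub-score bar chart
#'
#' @param object A `dm_hubs` tibble from [mcc_score()].
#' @param k Number of top hubs to show.
#' @param metric `"mcc"` or `"degree"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dm_hubs
#' @export
autoplot.dm_hubs <- function(object, k = 10, metric = c("mcc", "degree"),
                             ...) {
  metric <- match.arg(metric)
  df <- top_hubs(object, k = min(k, nrow(object)), metric = metric)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[metric]], y = .data$gene)) +
    ggplot2::geom_col(fill = "#7A9A01") +
    ggplot2::labs(x = metric, y = NULL) +
    ggplot2::theme_minimal()
}
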