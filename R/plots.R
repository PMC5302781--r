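#' Pareto chart of explained variance
#'
#' Bars of per-component explained variance with the cumulative line — the
#' standard view for deciding how many components carry the variation signal.
#'
#' @param object a `pca_result` from [pca_variation()].
#' @param n_components number of leading components to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, n_components = 10, ...) {
  d <- tidy(object) %>% head(n_components) %>%
    mutate(component = factor(.data$component, levels = .data$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_pct), fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_pct, group = 1),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_pct),
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Explained variance (%)",
                  title = "Variance explained by principal components") +
    ggplot2::theme_minimal()
}

#' Score plot of the first two components
#'
#' @param pca a `pca_result` from [pca_variation()].
#' @param highlight optional character vector of observation ids to label.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, highlight = NULL) {
  d <- as_tibble(as.data.frame(pca$scores), rownames = "id")
  d$highlight <- if (is.null(highlight)) FALSE else d$id %in% highlight
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_text(
      data = d[d$highlight, , drop = FALSE],
      ggplot2::aes(label = .data$id), vjust = -0.8, size = 3
    )
  }
  p
}

#' Degree distribution of an MMI network
#'
#' @param object an [mmi_network()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot mmi_network
#' @export
autoplot.mmi_network <- function(object, ...) {
  d <- node_degrees(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, fill = .data$role)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Degree (parallel edges counted)", y = "Nodes") +
    ggplot2::theme_minimal()
}

#' Heat-map style view of a sensitivity matrix
#'
#' @param s_matrix pairs-by-miRNAs matrix from [triplet_scan()].
#' @param max_pairs,max_mirnas cap on rows/columns drawn.
#' @return A ggplot object (tiles; light columns flag mediating miRNAs).
#' @export
plot_sensitivity_matrix <- function(s_matrix, max_pairs = 200, max_mirnas = 100) {
  m <- s_matrix[seq_len(min(nrow(s_matrix), max_pairs)),
                seq_len(min(ncol(s_matrix), max_mirnas)), drop = FALSE]
  d <- as_tibble(as.data.frame(m), rownames = "pair") %>%
    tidyr::pivot_longer(-"pair", names_to = "mirna", values_to = "S")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mirna, y = .data$pair,
                                  fill = .data$S)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "navy", midpoint = 0) +
    ggplot2::labs(x = "miRNA", y = "mRNA/lncRNA pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Abundance-share bar chart per condition
#'
#' @param object a [titration_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot titration_report
#' @export
autoplot.titration_report <- function(object, ...) {
  d <- object$isoforms %>%
    select("isoform_id", "has_site",
           normal = "share_normal_pct", cancer = "share_cancer_pct") %>%
    tidyr::pivot_longer(c("normal", "cancer"), names_to = "condition",
                        values_to = "share_pct")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$isoform_id, y = .data$share_pct,
                                  fill = .data$has_site)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "Share of total abundance (%)",
                  fill = "Carries match site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
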