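#' Plot a group-contrast result
#'
#' Displays each feature's evidence as -log10 of the permutation p-value
#' against the adjusted group difference, coloured by significance after
#' BH-FDR on the permutation p-values.
#'
#' @param object An `fc_contrast`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_contrast <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = -log10(.data$p_perm),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 na.value = "grey85") +
    ggplot2::labs(x = "Adjusted group difference",
                  y = expression(-log[10]~"permutation p"),
                  colour = paste0("q <= ", attr(object, "q")),
                  title = paste0(attr(object, "level") %||% "feature",
                                 "-level group contrast")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of network-level connectivity by group
#'
#' @param network_tbl Network-level feature table (`subject_id` + features).
#' @param phenotypes Phenotypes with `subject_id` and `group`.
#' @param features Features to show (default the 8 intra-network features
#'   present).
#' @return A ggplot object.
#' @export
plot_network_fc <- function(network_tbl, phenotypes, features = NULL) {
  if (is.null(features)) {
    features <- grep("^intra_", names(network_tbl), value = TRUE)
  }
  d <- dplyr::inner_join(network_tbl, phenotypes[, c("subject_id", "group")],
                         by = "subject_id")
  d <- tidyr::pivot_longer(d, dplyr::all_of(features),
                           names_to = "feature", values_to = "fc")
  d$feature <- factor(d$feature, levels = features)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$fc,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Mean Fisher-z connectivity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a connectivity matrix ordered by network
#'
#' @param m N x N connectivity matrix (r or z).
#' @param parc Matching `fc_parcellation`; nodes are ordered by canonical
#'   network blocks.
#' @return A ggplot object.
#' @export
plot_connectivity_matrix <- function(m, parc) {
  ord <- order(match(parc$network, RSN_ORDER), parc$node_id)
  mm <- m[ord, ord]
  d <- tidyr::expand_grid(i = seq_len(nrow(mm)), j = seq_len(ncol(mm)))
  d$value <- mm[cbind(d$i, d$j)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "FC",
                  title = "Connectivity ordered by network") +
    ggplot2::theme_minimal()
}
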