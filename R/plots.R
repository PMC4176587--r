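#' Plot fuzzy cluster centroid profiles
#'
#' One panel per cluster showing the centroid trajectory over the profile
#' coordinates; when the clustered profiles are supplied, hard-assigned
#' member genes are drawn underneath with transparency proportional to
#' membership.
#'
#' @param object An [fcm_fit()] object.
#' @param profiles Optional profile tibble or matrix the fit was computed
#'   from.
#' @param threshold Membership cut-off for drawing member genes.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot fcm_fit
#' @export
autoplot.fcm_fit <- function(object, profiles = NULL, threshold = 0.5, ...) {
  coords <- colnames(object$centroids)
  cent <- as_tibble(object$centroids, rownames = "cluster")
  cent <- tidyr::pivot_longer(cent, -"cluster", names_to = "coordinate",
                              values_to = "value")
  cent$coordinate <- factor(cent$coordinate, levels = coords)
  p <- ggplot2::ggplot(cent, ggplot2::aes(.data$coordinate, .data$value,
                                          group = .data$cluster))
  if (!is.null(profiles)) {
    m <- as_profile_matrix(profiles)
    ha <- hard_assignments(object, threshold)
    ha <- ha[!is.na(ha$cluster), ]
    memb <- as_tibble(m[ha$gene, , drop = FALSE], rownames = "gene")
    memb <- tidyr::pivot_longer(memb, -"gene", names_to = "coordinate",
                                values_to = "value")
    memb <- dplyr::left_join(memb, ha, by = "gene")
    memb$coordinate <- factor(memb$coordinate, levels = coords)
    p <- p + ggplot2::geom_line(
      data = memb,
      ggplot2::aes(group = .data$gene, alpha = .data$membership),
      colour = "grey55", linewidth = 0.2
    ) + ggplot2::scale_alpha(range = c(0.05, 0.4), guide = "none")
  }
  p +
    ggplot2::geom_line(colour = "#b2182b", linewidth = 0.9) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "profile value",
                  title = sprintf("Fuzzy c-means centroids (c = %d, m = %.3g)",
                                  object$c, object$m)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Volcano plot of a moderated differential-expression table
#'
#' @param object A [moderated_de()] tibble (columns `log2fc`, `p_adj`,
#'   `contrast`).
#' @param p_cut,lfc_cut Thresholds drawn and used for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_volcano <- function(object, p_cut = 1e-05, lfc_cut = 1, ...) {
  d <- dplyr::mutate(
    object,
    selected = .data$p_adj < p_cut & abs(.data$log2fc) >= lfc_cut
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p_adj),
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Heatmap of an integrated cross-study matrix
#'
#' Tiles the scaled log2 ratios with rows and columns in dendrogram leaf
#' order; the classic green (down) to red (up) scheme, missing cells blank.
#'
#' @param object An `integrated_matrix` from [build_heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot integrated_matrix
#' @export
autoplot.integrated_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$study, .data$gene,
                                  fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1a9641", mid = "black",
                                  high = "#d7191c", midpoint = 0,
                                  limits = object$range,
                                  na.value = "grey85",
                                  name = "log2 ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)
    )
}
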