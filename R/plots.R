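# ggplot2 views of the result objects.

#' @describeIn moderated_ttest Volcano plot, faceted by contrast; the
#'   significance rule's thresholds are drawn as reference lines.
#' @param object,alpha,lfc_threshold,... Method arguments.
#' @export
autoplot.surfmark_contrast <- function(object, alpha = 0.05,
                                       lfc_threshold = 2, ...) {
  dat <- tidy(object)
  if (!"significant" %in% names(dat)) dat$significant <- FALSE
  dat$p_plot <- if ("p_adj" %in% names(dat)) dat$p_adj else dat$p_raw
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$p_plot),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' @describeIn build_heatmap_set Tile heatmap of the z-scored intensities in
#'   dendrogram row order; missing (never-observed, never-imputed) cells are
#'   drawn gray.
#' @param object,... Method arguments.
#' @export
autoplot.heatmap_set <- function(object, ...) {
  z <- object$z %>%
    dplyr::mutate(protein_id = factor(.data$protein_id,
                                      levels = rev(object$row_order)))
  ggplot2::ggplot(z, ggplot2::aes(x = .data$sample_id, y = .data$protein_id,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of detection Venn regions
#'
#' @param profiles A [detection_profiles()] tibble.
#' @param sets Conditions forming the diagram.
#' @return A ggplot object.
#' @export
plot_detection_regions <- function(profiles, sets = c("BU", "BX", "BY")) {
  venn <- venn_partition(profiles, sets)
  ggplot2::ggplot(venn, ggplot2::aes(x = stats::reorder(.data$region,
                                                        -.data$n),
                                     y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "detection region", y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn overrepresentation Fold-enrichment bar chart of the
#'   significant terms.
#' @param object,alpha,... Method arguments.
#' @export
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  dat <- object %>% dplyr::filter(.data$p_bonferroni <= alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$term_id,
                                                       .data$fold_enrichment),
                                    y = .data$fold_enrichment,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment", fill = NULL) +
    ggplot2::theme_minimal()
}
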