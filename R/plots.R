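#' Volcano plot of a differential-expression result
#'
#' @param object A [moderated_paired_t()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(.data$p_value),
                               colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "DE call") +
    ggplot2::labs(x = "log2 fold change (A - B)",
                  y = "-log10 p (moderated t)") +
    ggplot2::theme_minimal()
}

#' Degree-difference overview of two networks
#'
#' TF out-degree differences as a ranked lollipop (positive = higher
#' targeting in group A) and, optionally restricted to a highlighted
#' gene set, the gene in-degree difference distribution.
#'
#' @param object A [degree_differences()] result.
#' @param highlight Optional character vector of genes to highlight in
#'   the in-degree panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.targeting_diff <- function(object, highlight = NULL, ...) {
  gene <- object$gene
  gene$set <- if (is.null(highlight)) "all genes" else {
    ifelse(gene$gene %in% highlight, "highlighted set", "other genes")
  }
  ggplot2::ggplot(gene, ggplot2::aes(x = .data$set, y = .data$diff)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "gene in-degree difference (A - B)") +
    ggplot2::theme_minimal()
}

#' Running-sum (mountain) plot for one gene set
#'
#' @param es An [enrichment_score()] result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_running_sum <- function(es, title = NULL) {
  ggplot2::ggplot(es$running,
                  ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(data = es$running[es$running$hit, ],
                      sides = "b", length = ggplot2::unit(0.02, "npc")) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "rank position", y = "running enrichment sum",
                  title = title) +
    ggplot2::theme_minimal()
}

#' TF-target correlation contrast boxplot
#'
#' @param object A [group_correlation_contrast()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cor_contrast <- function(object, ...) {
  ggplot2::ggplot(object$rho, ggplot2::aes(x = .data$group, y = .data$rho)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL,
                  y = paste0("Spearman rho (", object$tf, " vs bound genes)"),
                  subtitle = paste0("Wilcoxon p = ",
                                    signif(object$wilcox_p, 3))) +
    ggplot2::theme_minimal()
}
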