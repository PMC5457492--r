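#' Plot the fitted efficiency curve
#'
#' @param object An `efficiency_model`.
#' @param ... Unused.
#' @return A ggplot of predicted efficiency against signed TSS distance,
#'   with the peak distance marked.
#' @export
autoplot.efficiency_model <- function(object, ...) {
  grid <- tibble::tibble(d = seq(object$domain[1], object$domain[2],
                                 length.out = 400))
  grid$score <- predict_efficiency(object, grid$d)
  peak <- peak_efficiency_distance(object)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$d, y = .data$score)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = peak, linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "signed distance to TSS (bp)",
                  y = "predicted efficiency",
                  title = sprintf("Peak efficiency at %+d bp", round(peak))) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Volcano-style plot of gene essentiality scores
#'
#' @param scores Gene score tibble ([score_genes()]).
#' @param p_threshold Calling threshold drawn as a guide line (default 0.01).
#' @return A ggplot of mean guide fold-change against -log10 P.
#' @export
plot_gene_scores <- function(scores, p_threshold = 0.01) {
  scores$called <- scores$p < p_threshold
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$m_g,
                                       y = -log10(pmax(.data$p, 1e-300)),
                                       color = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d7301f",
                                           `FALSE` = "grey55")) +
    ggplot2::labs(x = "mean guide log2 fold-change",
                  y = "-log10 P (Z-test vs AAVS1)", color = "called") +
    ggplot2::theme_minimal()
}

#' Plot fold-change by target-multiplicity bin and modality
#'
#' @param summary Output of [multiplicity_effect()].
#' @return A ggplot of median fold-change (with IQR) per bin, split by
#'   modality.
#' @export
plot_multiplicity_effect <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$bin, y = .data$median_lfc,
                               color = .data$modality,
                               group = .data$modality)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "genomic target sites",
                  y = "guide log2 fold-change (median, IQR)") +
    ggplot2::theme_minimal()
}

#' Plot per-gene scores across an amplicon
#'
#' @param cas9_scan,krab_scan Outputs of [amplicon_scan()] for the two
#'   modalities over the same genes.
#' @return A ggplot comparing the two modalities gene by gene.
#' @export
plot_amplicon_scan <- function(cas9_scan, krab_scan) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(cas9_scan, modality = "cas9"),
    dplyr::mutate(krab_scan, modality = "krab_dcas9"))
  dat$gene <- factor(dat$gene, levels = cas9_scan$gene)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$score,
                                    fill = .data$modality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "mean guide log2 fold-change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
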