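#' Histogram of log2 fold changes with the MFV threshold
#'
#' @param fc_tbl Output of [select_mfv()].
#' @param bins Histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(fc_tbl, bins = 60) {
  thr <- mfv_threshold(fc_tbl)
  ggplot2::ggplot(fc_tbl, ggplot2::aes(x = .data$log2fc,
                                       fill = .data$is_mfv)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "MFV") +
    ggplot2::labs(x = "log2 fold change (cases / pseudocontrols)",
                  y = "variants",
                  subtitle = sprintf("MFV threshold %.2f", thr)) +
    ggplot2::theme_minimal()
}

#' Mean fold-change scatter of prioritized genes
#'
#' Mirrors the gene-prioritization view: each gene's mean log2 fold change
#' over benign variants (x) against deleterious variants (y), significant
#' genes highlighted.
#'
#' @param object A `gene_prior_result` from [prioritize_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_prior_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_fc_ben,
                                       y = .data$mean_fc_del,
                                       colour = .data$significant,
                                       shape = .data$panel)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "FDR < alpha") +
    ggplot2::labs(x = "mean log2(FC), benign variants",
                  y = "mean log2(FC), deleterious variants") +
    ggplot2::theme_minimal()
}

#' Carrier-frequency bar chart
#'
#' Top genes by carrier frequency in the pseudocontrols, ordered
#' decreasingly.
#'
#' @param cf_report Output of [carrier_frequency_report()].
#' @param top Number of genes shown (default 10).
#' @return A ggplot object.
#' @export
plot_carrier_frequencies <- function(cf_report, top = 10) {
  dat <- cf_report %>%
    arrange(desc(.data$cf_percent)) %>%
    head(top) %>%
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cf_percent, y = .data$gene)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "carrier frequency (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
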