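#' Volcano plot of a differential-expression result
#'
#' @param object A `credentor_de` tibble.
#' @param alpha FDR threshold highlighted.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.credentor_de <- function(object, alpha = 0.01, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$p_value))
  df$signif <- !is.na(df$padj) & df$padj < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p_value),
                                   colour = .data$signif)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste0("Differential cryptic transcript expression (FDR < ",
                                 alpha, " highlighted)")) +
    ggplot2::theme_minimal()
}

#' Plot observed vs permuted repeat-class overlap
#'
#' @param enrichment Output of [repeat_class_enrichment()].
#' @return A ggplot comparing the observed overlap fraction with the null
#'   mean +/- 2 sd per repeat class.
#' @export
plot_repeat_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment, ggplot2::aes(.data$repeat_class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_fraction),
                      fill = "firebrick", width = 0.6) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$null_mean,
      ymin = pmax(0, .data$null_mean - 2 * .data$null_sd),
      ymax = .data$null_mean + 2 * .data$null_sd)) +
    ggplot2::labs(x = NULL, y = "fraction of peaks overlapping class",
                  title = "Observed (bars) vs permuted (points) repeat overlap") +
    ggplot2::theme_minimal()
}

#' Histogram of summit positions along the repeat consensus
#'
#' @param profile Output of [positional_profile()].
#' @param bins Number of histogram bins over [0, 1].
#' @return A ggplot faceted by repeat family.
#' @export
plot_positional_profile <- function(profile, bins = 20) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$rel_pos,
                                        fill = .data$repeat_class)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = "relative position along consensus (0 = 5' end)",
                  y = "summits") +
    ggplot2::theme_minimal()
}

#' Signal distribution across motif methylation bins
#'
#' @param strata Output of [stratify_motifs_by_methylation()].
#' @return A ggplot of per-bin signal boxplots.
#' @export
plot_motif_methylation <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(.data$bin, .data$signal)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "methylation beta at core CpG", y = "mean signal depth",
                  title = "HRE motif signal stratified by CpG methylation") +
    ggplot2::theme_minimal()
}
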