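#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_col geom_tile
#'   labs facet_wrap scale_colour_manual autoplot theme_minimal
#' @export
ggplot2::autoplot

#' Regional association plot
#'
#' Marginal -log10 p-values along the region, with accepted signal leads
#' highlighted and the acceptance threshold drawn.
#'
#' @param stats Summary-statistics tibble (columns `pos`, `neglog10p`).
#' @param signals Optional `fm_signals`/signals tibble with `snp`, `pos`.
#' @param p_enter Threshold line (default 1e-6).
#' @return A ggplot object.
#' @export
plot_region <- function(stats, signals = NULL, p_enter = 1e-6) {
  p <- ggplot(stats, aes(x = .data$pos / 1e6, y = .data$neglog10p)) +
    geom_point(colour = "grey40", size = 1) +
    geom_hline(yintercept = -log10(p_enter), linetype = "dashed",
               colour = "firebrick") +
    labs(x = "Position (Mb)", y = expression(-log[10] * "(p)")) +
    theme_minimal()
  if (!is.null(signals) && nrow(signals) > 0) {
    p <- p + geom_point(data = as_tibble(signals),
                        aes(x = .data$pos / 1e6, y = .data$neglog10p),
                        colour = "firebrick", size = 2.5, shape = 18)
  }
  p
}

#' @rdname plot_region
#' @param object A `fm_signals` object.
#' @param stats Summary statistics used for the background points.
#' @param ... Unused.
#' @export
autoplot.fm_signals <- function(object, stats, ...) {
  plot_region(stats, object, p_enter = attr(object, "thresholds")$p_enter)
}

#' Gene-score bar plot
#'
#' Distal/proximal/coding scores per candidate gene, faceted by signal.
#'
#' @param object A `fm_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fm_scores <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("distal", "proximal", "coding"),
                        names_to = "class", values_to = "score")
  ggplot(long, aes(x = .data$gene_id, y = .data$score, fill = .data$class)) +
    geom_col(position = "dodge") +
    facet_wrap(~ .data$signal_id, scales = "free_x") +
    labs(x = NULL, y = "Evidence score", fill = "Link class") +
    theme_minimal()
}

#' SMR colocalization plot
#'
#' |z| of the GWAS instrument against |z| of the molecular-trait
#' association, significant colocalizations highlighted.
#'
#' @param object A `fm_smr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fm_smr <- function(object, ...) {
  ggplot(object, aes(x = abs(.data$z_qtl), y = abs(.data$z_gwas),
                     colour = .data$significant)) +
    geom_point(size = 2) +
    scale_colour_manual(values = c(`TRUE` = "firebrick",
                                   `FALSE` = "grey50")) +
    labs(x = "|z| molecular trait", y = "|z| GWAS",
         colour = "Colocalized") +
    theme_minimal()
}
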