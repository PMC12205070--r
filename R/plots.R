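#' Plot the stemness score distribution with its natural breaks
#'
#' Histogram of per-cell scores with the Jenks breaks as dashed lines and the
#' stem threshold highlighted.
#'
#' @param object A `stemness_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stemness_result
#' @export
autoplot.stemness_result <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$breaks, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::labs(x = "stemness score", y = "cells",
                  title = sprintf("Stem-like: %.2f%% (threshold %.3f, %s)",
                                  100 * mean(object$cells$stem),
                                  object$threshold, object$threshold_source)) +
    ggplot2::theme_minimal()
}

#' Forest plot of composition differences
#'
#' Point estimates and bootstrap intervals of the per-category log2
#' fold-difference between conditions.
#'
#' @param object A `proportion_test` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot proportion_test
#' @export
autoplot.proportion_test <- function(object, ...) {
  conds <- attr(object, "conditions") %||% c("A", "B")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fd, y = .data$category,
                               colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("log2FD (%s vs %s)", conds[2], conds[1]),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de Data frame with `log2fc`, `p_adjusted` (and optionally `gene`).
#' @param lfc_min,alpha Thresholds drawn and used to colour points.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, lfc_min = 0.5, alpha = 0.05) {
  de <- mutate(as_tibble(de),
               significant = abs(.data$log2fc) > lfc_min &
                 .data$p_adjusted < alpha)
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_adjusted, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Enrichment curve for one gene set
#'
#' Recomputes the running-sum walk of [preranked_gsea()] for a single set and
#' plots it with the hit positions as a rug.
#'
#' @param stats Named ranking vector (see [preranked_gsea()]).
#' @param gene_set Character vector of genes.
#' @param weight Walk exponent.
#' @return A ggplot.
#' @export
plot_enrichment <- function(stats, gene_set, weight = 1) {
  stats <- sort(stats, decreasing = TRUE)
  N <- length(stats)
  hits <- names(stats) %in% gene_set
  if (sum(hits) == 0) abort("Gene set does not overlap the ranking.")
  w <- abs(stats)^weight
  inc <- ifelse(hits, w / sum(w[hits]), 0)
  dec <- ifelse(hits, 0, 1 / (N - sum(hits)))
  walk <- cumsum(inc - dec)
  df <- tibble(rank = seq_len(N), running = walk, hit = hits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", colour = "black",
                      length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment score") +
    ggplot2::theme_minimal()
}
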