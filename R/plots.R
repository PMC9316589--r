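#' Plot hit-set sizes
#'
#' Bar chart of the per-timepoint call sets (A3..D3) and the time-specific
#' sets (A4..D4), faceted by direction.
#'
#' @param object A `chrono_hitcall` from [run_hitcall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrono_hitcall <- function(object, ...) {
  sz <- glance(object)
  df <- tibble::tibble(
    set = c("A3", "B3", "C3", "D3", "A4", "B4", "C4", "D4"),
    timepoint = rep(c("ZT16", "ZT16", "ZT28", "ZT28"), 2L),
    direction = rep(c("sensitivity", "resistance"), 4L),
    stage = rep(c("all calls", "time-specific"), each = 4L),
    genes = unlist(sz[c("A3", "B3", "C3", "D3", "A4", "B4", "C4", "D4")]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$genes,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = NULL, y = "genes", fill = NULL,
                  title = "Chrono-screen hit sets") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Horizontal bars of -log10(p) for the top pathways, annotated with the
#' hit ratio and raw p-value, in the layout conventional for screen KEGG
#' summaries.
#'
#' @param object A `screen_enrichment` from [enrich()].
#' @param top_n Number of top (smallest p) sets to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_enrichment <- function(object, top_n = 10, ...) {
  df <- head(dplyr::arrange(tibble::as_tibble(object), .data$p), top_n)
  df$label <- sprintf("%d/%d (p = %.2g)", df$k, df$n, df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p),
                                   y = stats::reorder(.data$set, -.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.05,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.35))) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise sample correlations
#'
#' @param qc A `screen_qc` from [qc_report()].
#' @param metric `"pearson"` or `"spearman"`.
#' @return A ggplot object.
#' @export
plot_sample_correlations <- function(qc, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  df <- qc$correlations
  if (nrow(df) == 0L) {
    abort("no correlation block (single-sample QC)")
  }
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, sample_a = "sample_b", sample_b = "sample_a"),
    tibble::tibble(sample_a = unique(c(df$sample_a, df$sample_b)),
                   sample_b = unique(c(df$sample_a, df$sample_b)),
                   pearson = 1, spearman = 1))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[metric]])),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = metric) +
    ggplot2::theme_minimal()
}
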