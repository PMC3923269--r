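# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot top k-mer enrichment ratios
#'
#' Bar chart of the highest-ranked k-mers by enrichment ratio; a ratio of
#' 1 (dashed line) means no enrichment over the source library.
#'
#' @param object A `syne_enrichment` from [enrichment_ratio()].
#' @param top_n Number of k-mers to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syne_enrichment <- function(object, top_n = 20L, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$kmer, .data$ratio), y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "enrichment ratio (sample / source library)",
      title = sprintf("Top %d-mers: %s vs %s", attr(object, "k"),
                      attr(object, "sample_id"), attr(object, "reference_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cluster-size spectrum
#'
#' Histogram of cumulative cluster frequencies on a log10 x-axis. An
#' unenriched random library collapses onto small clusters; enriched
#' samples grow a heavy tail of large clusters.
#'
#' @param object A `syne_clusters` from [build_clusters()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syne_clusters <- function(object, ...) {
  df <- cluster_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cumulative)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "cumulative cluster frequency", y = "clusters",
      title = sprintf("Cluster sizes, sample %s (%d clusters)",
                      attr(object, "sample_id"), attr(object, "n_clusters"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample complexity statistics
#'
#' Side-by-side bars of % unique and % clustered per sample — the
#' at-a-glance view of enrichment across a screen.
#'
#' @param summary Tibble from [summarize_samples()] / [summarize_counts()].
#' @return A ggplot.
#' @export
plot_summary <- function(summary) {
  df <- summary |>
    tidyr::pivot_longer(c("pct_unique", "pct_clustered"),
                        names_to = "statistic", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$pct, fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(pct_unique = "steelblue", pct_clustered = "tomato"),
      labels = c(pct_unique = "% unique", pct_clustered = "% clustered")) +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
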