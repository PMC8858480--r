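#' Scatter plot of co-mention count against normalized fraction
#'
#' Mirrors the standard literature-specificity view: each point is a drug,
#' x is the number of publications co-mentioning it with the term (log
#' scale), y is the fraction of the drug's literature devoted to the term.
#' Drugs in the upper right are both frequently and specifically
#' co-mentioned.
#'
#' @param table Association tibble from [associate()].
#' @param label_top Label the `label_top` highest-scoring drugs (0 = none).
#' @return A ggplot object.
#' @export
plot_association <- function(table, label_top = 10L) {
  stopifnot(is.data.frame(table))
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$count, y = .data$fraction)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$score), alpha = 0.6,
                        colour = "#2c7fb8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "publications co-mentioning drug and term",
      y = "fraction of drug's publications matching term",
      size = "score"
    ) +
    ggplot2::theme_minimal()
  if (label_top > 0 && nrow(table) > 0) {
    top <- head(arrange(table, desc(.data$score)), label_top)
    p <- p + ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data$drug),
      vjust = -0.6, size = 3, check_overlap = TRUE
    )
  }
  p
}

#' Violin plot of benchmark metric distributions
#'
#' Observed per-term AUROC / average-precision distributions side by side
#' with the pooled shuffled-matrix null.
#'
#' @param result A `drug_benchmark` from [run_benchmark()].
#' @param metric `"auroc"`, `"avg_precision"`, or `"both"` (default).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(result, metric = c("both", "auroc", "avg_precision")) {
  stopifnot(inherits(result, "drug_benchmark"))
  metric <- match.arg(metric)
  d <- tidy(result)
  if (metric != "both") d <- filter(d, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$value,
                                  fill = .data$source)) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.1, fill = "white", outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = c("observed" = "#2c7fb8",
                                          "shuffled null" = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "per-term metric") +
    ggplot2::theme_minimal()
}

#' @method autoplot drug_benchmark
#' @export
autoplot.drug_benchmark <- function(object, ...) plot_benchmark(object, ...)
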