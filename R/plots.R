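#' Bar chart of the seven transcript classes
#'
#' @param annotations From [annotate_alignments()].
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(annotations) {
  lev <- c("FSM", "ISM", "NIC", "NNC", "Genic", "Intergenic", "Fusion",
           "Unmapped")
  d <- annotations |>
    count(.data$class) |>
    mutate(class = factor(.data$class, levels = lev))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Transcript class distribution") +
    ggplot2::theme_minimal()
}

#' Junction short-read support plot
#'
#' @param support From [junction_support()].
#' @return A ggplot object.
#' @export
plot_junction_support <- function(support) {
  ggplot2::ggplot(support, ggplot2::aes(x = .data$support,
                                        fill = .data$supported)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::labs(x = "spanning short reads", y = "junctions",
                  title = "RNA-seq junction support") +
    ggplot2::theme_minimal()
}

#' Plot a differential-isoform-usage result
#'
#' Isoform count vs. -log10 q-value per tested gene.
#'
#' @param object A `diu_result`.
#' @param fdr Significance threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diu_result <- function(object, fdr = 0.05, ...) {
  d <- tidy(object) |>
    mutate(neglog_q = -log10(pmax(.data$q_value, 1e-300)),
           significant = .data$q_value < fdr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data$neglog_q,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::labs(x = "isoforms per gene", y = "-log10(q)",
                  title = "Differential isoform usage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
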