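# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a size profile
#'
#' Smoothed 1-bp size histogram with the top modal sizes marked.
#'
#' @param profile An `ecc_size_profile`.
#' @param n_peaks Number of top peaks to annotate.
#' @return A ggplot object.
#' @export
plot_size_profile <- function(profile, n_peaks = 2) {
  top <- utils::head(profile$peaks, n_peaks)
  ggplot2::ggplot(profile$histogram, ggplot2::aes(.data$size, .data$smoothed)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = top$size, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = profile$median, linetype = "dotted") +
    ggplot2::labs(x = "eccDNA size (bp)", y = "smoothed count",
                  title = paste0("Size distribution (median ",
                                 profile$median, " bp)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecc_size_profile <- function(object, ...) plot_size_profile(object, ...)

#' Plot element enrichment scores
#'
#' Normalized per-class junction enrichment; the dashed line at 1 marks the
#' uniform-placement expectation.
#'
#' @param enrichment An `ecc_enrichment` tibble.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(
    enrichment,
    ggplot2::aes(stats::reorder(.data$class, .data$normalized_score),
                 .data$normalized_score)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized junction enrichment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecc_enrichment <- function(object, ...) plot_enrichment(object, ...)

#' Plot a genome-wide bin distribution
#'
#' Per-bin normalized call density along each chromosome.
#'
#' @param bins An `ecc_bins` tibble.
#' @return A ggplot object.
#' @export
plot_bin_distribution <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin_start / 1e6, .data$fraction)) +
    ggplot2::geom_col(width = attr(bins, "bin_width") / 1e6,
                      fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "fraction of calls") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecc_bins <- function(object, ...) plot_bin_distribution(object, ...)

#' Plot observed vs null enhancer scores
#'
#' Paired per-sample normalized enhancer scores for the observed joined
#' regions and the random-region null.
#'
#' @param test An `ecc_enhancer_test`.
#' @return A ggplot object.
#' @export
plot_enhancer_test <- function(test) {
  long <- test$scores |>
    pivot_longer(c("observed", "null"), names_to = "set",
                 values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(.data$set, .data$score,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set), size = 2) +
    ggplot2::labs(
      x = NULL, y = "normalized enhancer score",
      subtitle = paste0("one-tailed exact signed-rank p = ",
                        format(round(test$p_value, 3)))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.ecc_enhancer_test <- function(object, ...) plot_enhancer_test(object, ...)
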