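#' Plot a percentile-recall bias curve
#'
#' Recall per distance percentile, optionally smoothed with a centered
#' rolling mean, as used to visualize coverage- or composition-distance bias
#' in binning.
#'
#' @param percentiles Tibble from [percentile_recall()].
#' @param window Rolling-mean window (odd; 1 disables smoothing).
#' @return A ggplot object.
#' @export
plot_percentile_recall <- function(percentiles, window = 5L) {
  df <- dplyr::arrange(percentiles, .data$percentile)
  df$smoothed <- rolling_mean(df$recall, window)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$recall), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8) +
    ggplot2::labs(x = "distance percentile", y = "recall") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

rolling_mean <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, 0)
}

#' Plot per-genome evaluation metrics
#'
#' Boxplots of recall, precision, and F-score by pipeline.
#'
#' @param evals Evaluation tibble from [evaluate_bins()].
#' @return A ggplot object.
#' @export
plot_genome_eval <- function(evals) {
  long <- tidyr::pivot_longer(evals, c("recall", "precision", "fscore"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pipeline, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot simulated versus original pairwise beta diversity
#'
#' Scatter of the aligned pair distances with the fitted line from
#' [paired_beta_regression()].
#'
#' @param fit A `paired_beta_fit`.
#' @return A ggplot object.
#' @export
plot_paired_beta <- function(fit) {
  df <- tibble::tibble(orig = fit$model$model$orig_pairwise,
                       sim = fit$model$model$sim_pairwise)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$orig, y = .data$sim)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(x = "original pairwise dissimilarity",
                  y = "simulated pairwise dissimilarity",
                  subtitle = sprintf("slope %.2f, R² %.2f",
                                     fit$slope, fit$r_squared)) +
    ggplot2::theme_minimal()
}
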