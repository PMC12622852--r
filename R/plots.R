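#' Score distribution plot
#'
#' Histogram of HRD scores with the positivity cutoff marked; the scar
#' classifier is designed to produce a near-binary, bimodal distribution.
#'
#' @param data tibble with a `score` column (e.g. a scored manifest).
#' @param cutoff positivity cutoff to annotate.
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_score_distribution <- function(data, cutoff = 0.7, bins = 40) {
  d <- data[!is.na(data$score), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "HRD score", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Dilution-series plot
#'
#' Hit rate (with Wilson interval) against the dilution level, one panel per
#' specimen, annotated with the mean adjusted tumor purity.
#'
#' @param levels output of [dilution_level_summary()].
#' @param hit_threshold threshold line to draw.
#' @return a ggplot object.
#' @export
plot_dilution_series <- function(levels, hit_threshold = 0.95) {
  ggplot2::ggplot(levels, ggplot2::aes(x = .data$level, y = .data$hit_rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hit_lower,
                                      ymax = .data$hit_upper), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = hit_threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~specimen_id) +
    ggplot2::labs(x = "target tumor purity (dilution level)",
                  y = "hit rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Feature-importance plot for a fitted HRD model
#'
#' @param object an `hrd_model`.
#' @param top_n number of features to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot hrd_model
autoplot.hrd_model <- function(object, top_n = 20, ...) {
  imp <- tidy(object) |> slice_head(n = top_n)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$gain,
                                    y = stats::reorder(.data$feature, .data$gain))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "gain", y = NULL) +
    ggplot2::theme_minimal()
}
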