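#' Box plots of model accuracy by predictor set, approach and regime
#'
#' @param eval_records Eval-record tibble from [run_experiment()].
#' @param metric Metric column to display.
#' @return A ggplot object.
#' @export
plot_performance <- function(eval_records, metric = "auc") {
  ggplot2::ggplot(eval_records,
                  ggplot2::aes(x = .data$predictor_set, y = .data[[metric]],
                               fill = .data$approach)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~eval_type) +
    ggplot2::labs(x = NULL, y = toupper(metric), fill = "approach") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat map of mean Schoener's D between predictor sets
#'
#' @param overlap Overlap tibble from [run_experiment()] (`set_a`, `set_b`,
#'   `mean_d`, `epoch`).
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap) {
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = .data$set_a, y = .data$set_b,
                               fill = .data$mean_d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_d)),
                       size = 2.6) +
    ggplot2::facet_wrap(~epoch) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean D") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box plots of accuracy aggregated by species traits
#'
#' @param eval_records Eval-record tibble.
#' @param traits Trait columns to panel.
#' @param metric Metric column.
#' @return A ggplot object.
#' @export
plot_trait_performance <- function(eval_records,
                                   traits = c("origin", "phenology",
                                              "specialization", "preference"),
                                   metric = "auc") {
  long <- eval_records |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data[[metric]],
                                     fill = .data$level)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3,
                          show.legend = FALSE) +
    ggplot2::facet_grid(trait ~ eval_type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_bw()
}

#' Plot a raster grid
#'
#' @param object A [raster_grid()] (e.g. a suitability map).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- cell_centres(object)
  df$value <- object$values[cbind(df$row, df$col)]
  df$value[object$nodata_mask[cbind(df$row, df$col)]] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
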