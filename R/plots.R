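# ggplot2 views of the main result types.

#' Plot a threshold sweep
#'
#' AUROC against the target UMI threshold, one line per classifier, faceted
#' by label granularity; the untransformed control is drawn as an open point
#' at the right edge and the AUROC cutoff as a dashed line.
#'
#' @param object A `sweep_result`.
#' @param cutoff AUROC cutoff to draw (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, cutoff = 0.9, ...) {
  d <- tidy(object)
  swept <- d |> filter(!is.na(.data$threshold))
  control <- d |>
    filter(is.na(.data$threshold)) |>
    mutate(threshold = max(swept$threshold) * 1.08)
  ggplot(swept, aes(x = .data$threshold, y = .data$auroc,
    colour = .data$classifier)) +
    geom_hline(yintercept = cutoff, linetype = "dashed", colour = "grey40") +
    geom_line() +
    geom_point(size = 1.4) +
    geom_point(data = control, shape = 1, size = 2.4) +
    facet_wrap(~granularity) +
    labs(x = "target UMI threshold", y = "multiclass AUROC",
      colour = NULL) +
    theme_bw()
}

#' Plot per-class rescue gains
#'
#' Bar plot of the percentage of cells gained per class after applying the
#' optimized threshold, faceted by granularity.
#'
#' @param object A `rescue_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rescue_report <- function(object, ...) {
  d <- tidy(object) |> filter(.data$status == "gain")
  ggplot(d, aes(x = stats::reorder(.data$label, -.data$percent_gain),
    y = .data$percent_gain)) +
    geom_col(fill = "seagreen4") +
    facet_wrap(~granularity, scales = "free_x") +
    labs(
      x = NULL, y = "cells gained (% of initially retained)",
      title = sprintf("Threshold %d → %d", object$initial_threshold,
        object$optimized_threshold)
    ) +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Per-cell QC scatter
#'
#' Total UMIs against expressed genes, coloured by the QC partition, with the
#' UMI floor drawn; the standard view of how a depth threshold splits the
#' population.
#'
#' @param stats Cell stats with a `partition` column ([apply_qc()]).
#' @param thresholds The [qc_thresholds()] used (for the drawn floor).
#' @return A ggplot object.
#' @export
plot_qc_partition <- function(stats, thresholds = qc_thresholds()) {
  ggplot(stats, aes(x = .data$total_umis, y = .data$n_genes,
    colour = .data$partition)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = thresholds$min_umis, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "total UMIs", y = "expressed genes", colour = NULL) +
    theme_bw()
}
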