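# Applying the optimized threshold: rescue the depth-failed cells that now
# qualify, classify them, and account for the gains.

#' Rescue and classify low-depth cells under an optimized threshold
#'
#' Cells in the QC `rescue_pool` (depth/gene-floor failures only) whose total
#' UMI count exceeds `t_opt` are rescued and classified by the supplied
#' model(s). Gains are tabulated per class against the initially retained
#' (high-quality) cells, whose classes come from `hq_labels`; rescued cells'
#' classes come from the classifier calls, since their ground truth is
#' unknown in real data. If `truth` is given (synthetic data), a
#' truth-vs-call agreement table is added.
#'
#' @param m Genes x cells count matrix of all cells (full dataset).
#' @param stats Cell stats with a `partition` column, from [apply_qc()].
#' @param models A list of trained models (typically one per granularity).
#' @param t_opt Optimized UMI threshold; must be below the initial
#'   `min_umis` used for `stats`.
#' @param hq_labels Label table for the high-quality cells at every
#'   granularity the models cover.
#' @param initial_threshold The initial `min_umis` (default 1500), used for
#'   validation and reporting.
#' @param sample_ids Optional tibble (`cell_barcode`, `sample_id`) for
#'   per-sample composition tables.
#' @param truth Optional label table with the rescued cells' true labels.
#' @return An object of class `rescue_report`; see [tidy.rescue_report()].
#' @export
rescue_cells <- function(m, stats, models, t_opt, hq_labels,
                         initial_threshold = 1500, sample_ids = NULL,
                         truth = NULL) {
  m <- as_count_matrix(m)
  if (!"partition" %in% names(stats)) {
    abort("`stats` must carry the `partition` column from apply_qc()")
  }
  if (t_opt >= initial_threshold) {
    abort("`t_opt` must be below the initial threshold (nothing to rescue)")
  }
  hq_labels <- validate_labels(hq_labels)
  pool <- stats |> filter(.data$partition == "rescue_pool")
  rescued <- pool |> filter(.data$total_umis > t_opt)
  still_excluded <- pool |> filter(.data$total_umis <= t_opt)

  rescued_labels <- list()
  for (mod in models) {
    gran <- attr(mod, "granularity")
    if (nrow(rescued)) {
      sm <- predict_cells(mod, m[, rescued$cell_barcode, drop = FALSE])
      rescued_labels[[gran]] <- tibble(
        cell_barcode = rescued$cell_barcode,
        label = unname(sm$call[rescued$cell_barcode]),
        granularity = gran
      )
    } else {
      rescued_labels[[gran]] <- tibble(cell_barcode = character(),
        label = character(), granularity = character())
    }
  }
  rescued_labels <- list_rbind(rescued_labels)

  initial_counts <- hq_labels |>
    filter(.data$cell_barcode %in%
        stats$cell_barcode[stats$partition == "high_quality"]) |>
    count(.data$granularity, .data$label, name = "initial_count")
  rescued_counts <- rescued_labels |>
    count(.data$granularity, .data$label, name = "rescued_count")
  gains <- full_join(initial_counts, rescued_counts,
    by = c("granularity", "label")) |>
    mutate(
      initial_count = coalesce(.data$initial_count, 0L),
      rescued_count = coalesce(.data$rescued_count, 0L),
      percent_gain = ifelse(.data$initial_count > 0,
        100 * .data$rescued_count / .data$initial_count, NA_real_),
      status = ifelse(.data$initial_count > 0, "gain", "new")
    ) |>
    arrange(.data$granularity, .data$label)

  composition <- NULL
  if (!is.null(sample_ids)) {
    before <- hq_labels |>
      filter(.data$cell_barcode %in%
          stats$cell_barcode[stats$partition == "high_quality"])
    after <- bind_rows(before, rescued_labels)
    comp_tab <- function(tab, when) {
      tab |>
        select(-dplyr::any_of("sample_id")) |>
        inner_join(sample_ids, by = "cell_barcode") |>
        count(.data$sample_id, .data$granularity, .data$label) |>
        group_by(.data$sample_id, .data$granularity) |>
        mutate(frequency = .data$n / sum(.data$n), when = when) |>
        ungroup() |>
        select(-"n")
    }
    composition <- bind_rows(comp_tab(before, "before"),
      comp_tab(after, "after"))
  }

  agreement <- NULL
  if (!is.null(truth) && nrow(rescued)) {
    truth <- validate_labels(truth)
    agreement <- rescued_labels |>
      inner_join(truth, by = c("cell_barcode", "granularity"),
        suffix = c("_call", "_truth")) |>
      count(.data$granularity, .data$label_truth, .data$label_call)
  }

  structure(
    list(
      optimized_threshold = as.integer(t_opt),
      initial_threshold = as.integer(initial_threshold),
      gains = gains,
      rescued_labels = rescued_labels,
      rescued_barcodes = rescued$cell_barcode,
      n_rescued = nrow(rescued),
      n_still_excluded = nrow(still_excluded),
      n_initial = sum(stats$partition == "high_quality"),
      composition = composition,
      agreement = agreement
    ),
    class = "rescue_report"
  )
}

#' @export
print.rescue_report <- function(x, ...) {
  cat(sprintf(
    "<rescue_report> threshold %d -> %d: %d initially retained, %d rescued (+%.1f%%), %d still excluded\n",
    x$initial_threshold, x$optimized_threshold, x$n_initial, x$n_rescued,
    100 * x$n_rescued / max(1, x$n_initial), x$n_still_excluded
  ))
  invisible(x)
}

#' Tidy the per-class gains of a rescue report
#'
#' @param x A `rescue_report`.
#' @param ... Unused.
#' @return The gains tibble: `granularity`, `label`, `initial_count`,
#'   `rescued_count`, `percent_gain`, `status`.
#' @export
tidy.rescue_report <- function(x, ...) x$gains

#' @export
glance.rescue_report <- function(x, ...) {
  tibble(
    initial_threshold = x$initial_threshold,
    optimized_threshold = x$optimized_threshold,
    n_initial = x$n_initial,
    n_rescued = x$n_rescued,
    n_still_excluded = x$n_still_excluded,
    percent_gain = 100 * x$n_rescued / max(1, x$n_initial)
  )
}
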