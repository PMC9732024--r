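# Per-cell QC statistics, the three-way QC partition, and the cell-type ->
# lineage aggregation map.

#' Per-cell quality-control statistics
#'
#' Computes, for every cell of a genes x cells UMI matrix: the total UMI
#' count, the number of expressed genes (count >= 1), and the mitochondrial
#' fraction (share of UMIs on genes whose name starts with `mito_prefix`;
#' defined as 0 for cells with zero total).
#'
#' @param m Genes x cells count matrix.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes
#'   (human convention `"MT-"`).
#' @return A tibble with columns `cell_barcode`, `total_umis`, `n_genes`,
#'   `mito_fraction`, in matrix column order.
#' @export
compute_cell_stats <- function(m, mito_prefix = "MT-") {
  m <- as_count_matrix(m)
  stopifnot(is.character(mito_prefix), nchar(mito_prefix) > 0)
  totals <- cell_totals(m)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_counts <- if (any(mito)) cell_totals(m[mito, , drop = FALSE]) else 0
  tibble(
    cell_barcode = colnames(m),
    total_umis = as.integer(totals),
    n_genes = as.integer(cells_n_genes(m)),
    mito_fraction = as.numeric(ifelse(totals > 0, mito_counts / totals, 0))
  )
}

#' QC thresholds
#'
#' The stringent "gold standard" filter: keep cells with more than `min_umis`
#' UMIs, `min_genes`--`max_genes` expressed genes (inclusive), a mitochondrial
#' fraction strictly below `max_mito`, and at most `doublet_umi_cap` UMIs
#' (cells above the cap are treated as putative doublets).
#'
#' @param min_umis,min_genes,max_genes,max_mito,doublet_umi_cap Filter bounds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umis = 1500, min_genes = 500, max_genes = 7000,
                          max_mito = 0.20, doublet_umi_cap = 15000) {
  stopifnot(min_umis >= 0, min_genes <= max_genes,
    max_mito >= 0, max_mito <= 1)
  structure(
    list(min_umis = min_umis, min_genes = min_genes, max_genes = max_genes,
      max_mito = max_mito, doublet_umi_cap = doublet_umi_cap),
    class = "qc_thresholds"
  )
}

#' Partition cells into high-quality / rescue-pool / excluded sets
#'
#' `high_quality` cells pass every filter. Cells failing the mitochondrial
#' rule, the doublet UMI cap, or the gene ceiling are `excluded` and are never
#' rescuable: the framework optimizes only the depth threshold, so only cells
#' whose sole failure is the UMI/gene floor land in the `rescue_pool`.
#'
#' @param stats Cell-stats tibble from [compute_cell_stats()].
#' @param thresholds A [qc_thresholds()] object.
#' @return `stats` with an added `partition` factor
#'   (`high_quality`, `rescue_pool`, `excluded`); levels form a disjoint,
#'   exhaustive cover of the cells.
#' @export
apply_qc <- function(stats, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  t <- thresholds
  stats |>
    mutate(
      partition = factor(
        case_when(
          .data$mito_fraction >= t$max_mito ~ "excluded",
          .data$total_umis > t$doublet_umi_cap ~ "excluded",
          .data$n_genes > t$max_genes ~ "excluded",
          .data$total_umis > t$min_umis & .data$n_genes >= t$min_genes ~
            "high_quality",
          TRUE ~ "rescue_pool"
        ),
        levels = c("high_quality", "rescue_pool", "excluded")
      )
    )
}

#' Default cell-type to lineage aggregation map
#'
#' The fixed coarse-graining used throughout: epithelial cells are their own
#' lineage; fibroblasts, endothelial cells, chondrocytes, osteoblasts and
#' smooth muscle are stromal; T-cells, B-cells, macrophages, monocytes, NK
#' cells and neutrophils are immune.
#'
#' @return A tibble with columns `cell_type`, `lineage`.
#' @export
default_lineage_map <- function() {
  tibble(
    cell_type = c(
      "epithelial cells",
      "fibroblasts", "endothelial cells", "chondrocytes", "osteoblast",
      "smooth muscles",
      "T-cells", "B-cells", "macrophages", "monocytes", "NK cells",
      "neutrophils"
    ),
    lineage = c(
      "epithelial",
      rep("stromal", 5),
      rep("immune", 6)
    )
  )
}

#' Aggregate cell-type labels into lineage labels
#'
#' @param labels A label table at `cell_type` granularity.
#' @param map A tibble with columns `cell_type`, `lineage` (one lineage per
#'   cell type); defaults to [default_lineage_map()].
#' @param strict If `TRUE` (default), an unmapped cell-type label is an error;
#'   if `FALSE`, unmapped labels become lineage `"unassigned"`.
#' @return A label table at `lineage` granularity with the same number of
#'   rows, in input order.
#' @export
aggregate_to_lineage <- function(labels, map = default_lineage_map(),
                                 strict = TRUE) {
  labels <- validate_labels(labels)
  if (any(labels$granularity != "cell_type")) {
    abort("`labels` must be at cell_type granularity")
  }
  if (anyDuplicated(map$cell_type)) abort("`map` maps a cell type twice")
  unmapped <- setdiff(unique(labels$label), map$cell_type)
  if (length(unmapped) && strict) {
    abort(sprintf(
      "cell-type label(s) not in the lineage map: %s",
      paste(unmapped, collapse = ", ")
    ))
  }
  lineage <- map$lineage[match(labels$label, map$cell_type)]
  labels |>
    mutate(
      label = coalesce(lineage, "unassigned"),
      granularity = "lineage"
    )
}
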