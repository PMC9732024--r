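# Synthetic multi-cell-type UMI count data with the statistical structure
# the framework assumes: type-specific log-normal depth tiers (deep
# epithelial-like cells, shallow lymphocyte-like cells), disjoint planted
# marker genes per type, mitochondrial genes, gamma-Poisson
# (negative-binomial) count noise, and a low-quality / low-depth cell tail
# with boosted mitochondrial content.

#' Simulation configuration
#'
#' The default emulates a tumor-like mixture of four cell types across three
#' lineages with depth tiers of roughly 5,300 / 3,100 / 2,100 / 1,800 mean
#' UMIs (epithelial > stromal > immune), so the deep types mostly clear a
#' 1,500-UMI floor while a sizeable fraction of the lymphocyte-like types
#' falls below it. `depth_log_mean` is the log-scale mean of the log-normal
#' depth, so the realized mean depth is `exp(depth_log_mean +
#' depth_log_sd^2 / 2)`.
#'
#' @param n_genes Total genes, including mitochondrial ones.
#' @param n_mito_genes Mitochondrial genes (named with the `MT-` prefix).
#' @param cell_types Tibble with columns `name`, `lineage`, `n_cells`,
#'   `depth_log_mean`, `depth_log_sd`, `marker_gene_count`, `marker_fold`.
#' @param baseline_dispersion Gamma-Poisson dispersion (0 = pure Poisson).
#' @param low_quality_fraction Fraction of cells in the low-quality tail.
#' @param low_quality_depth_factor Multiplier (< 1) on a low-quality cell's
#'   depth.
#' @param low_quality_mito_boost Multiplier (>= 1) on a low-quality cell's
#'   mitochondrial expression weight.
#' @param n_samples Number of sample (tumor) identifiers cells are spread
#'   over.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1500, n_mito_genes = 13,
                       cell_types = default_sim_cell_types(),
                       baseline_dispersion = 0.1,
                       low_quality_fraction = 0.25,
                       low_quality_depth_factor = 0.3,
                       low_quality_mito_boost = 4,
                       n_samples = 4, seed = 1L) {
  stopifnot(
    n_genes > 0, n_mito_genes >= 0, n_mito_genes < n_genes,
    baseline_dispersion >= 0,
    low_quality_fraction >= 0, low_quality_fraction < 1,
    low_quality_depth_factor > 0, low_quality_depth_factor < 1,
    low_quality_mito_boost >= 1, n_samples >= 1
  )
  cell_types <- as_tibble(cell_types)
  needed <- c("name", "lineage", "n_cells", "depth_log_mean", "depth_log_sd",
    "marker_gene_count", "marker_fold")
  missing <- setdiff(needed, names(cell_types))
  if (length(missing)) {
    abort(sprintf("`cell_types` is missing column(s): %s",
      paste(missing, collapse = ", ")))
  }
  if (sum(cell_types$n_cells) <= 0) abort("no cells configured")
  if (sum(cell_types$marker_gene_count) > n_genes - n_mito_genes) {
    abort("marker genes exceed the available non-mitochondrial genes")
  }
  structure(
    list(n_genes = n_genes, n_mito_genes = n_mito_genes,
      cell_types = cell_types, baseline_dispersion = baseline_dispersion,
      low_quality_fraction = low_quality_fraction,
      low_quality_depth_factor = low_quality_depth_factor,
      low_quality_mito_boost = low_quality_mito_boost,
      n_samples = n_samples, seed = seed),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_cell_types <- function() {
  sd <- 0.5
  mu <- function(mean) log(mean) - sd^2 / 2
  tibble(
    name = c("epithelial cells", "fibroblasts", "T-cells", "B-cells"),
    lineage = c("epithelial", "stromal", "immune", "immune"),
    n_cells = 500L,
    depth_log_mean = mu(c(5300, 3100, 2100, 1800)),
    depth_log_sd = sd,
    marker_gene_count = 30L,
    marker_fold = 10
  )
}

#' Simulate a labelled multi-cell-type UMI count dataset
#'
#' Per cell: a depth is drawn log-normal from its type's tier (times
#' `low_quality_depth_factor` for the low-quality tail); expression weights
#' are a shared log-normal baseline with the type's planted markers
#' up-weighted by `marker_fold` and, for low-quality cells, mitochondrial
#' genes up-weighted by `low_quality_mito_boost`; counts are gamma-Poisson
#' draws whose expected column sum equals the drawn depth.
#'
#' @param cfg A [sim_config()].
#' @return A list with `matrix` (sparse genes x cells counts) and `truth`
#'   (tibble: `cell_barcode`, `cell_type`, `lineage`, `sample_id`,
#'   `intended_depth`, `low_quality`). The planted markers are attached as
#'   attribute `"planted_markers"` (tibble `cell_type`, `gene`) of the
#'   returned list.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  types <- cfg$cell_types
  n_mito <- cfg$n_mito_genes
  genes <- c(
    if (n_mito > 0) paste0("MT-", seq_len(n_mito)) else character(),
    sprintf("GENE%04d", seq_len(cfg$n_genes - n_mito))
  )
  mito <- seq_len(n_mito)
  base <- rlnorm(cfg$n_genes, 0, 1)
  if (n_mito > 0) {
    # mitochondrial genes carry ~5% of a healthy cell's expression
    base[mito] <- base[mito] / sum(base[mito]) *
      (0.05 / 0.95) * sum(base[-mito])
  }
  # plant disjoint marker blocks on non-mito genes
  avail <- setdiff(seq_len(cfg$n_genes), mito)
  marker_idx <- list()
  offset <- 0
  for (k in seq_len(nrow(types))) {
    n_mark <- types$marker_gene_count[k]
    marker_idx[[types$name[k]]] <- avail[offset + seq_len(n_mark)]
    offset <- offset + n_mark
  }
  planted <- imap(marker_idx, function(ix, nm) {
    tibble(cell_type = nm, gene = genes[ix])
  }) |> list_rbind()

  n_total <- sum(types$n_cells)
  barcodes <- sprintf("cell%05d", seq_len(n_total))
  truth <- list()
  blocks <- list()
  pos <- 0
  for (k in seq_len(nrow(types))) {
    n <- types$n_cells[k]
    cells <- barcodes[pos + seq_len(n)]
    pos <- pos + n
    lq <- runif(n) < cfg$low_quality_fraction
    depth <- rlnorm(n, types$depth_log_mean[k], types$depth_log_sd[k])
    depth[lq] <- depth[lq] * cfg$low_quality_depth_factor
    w <- base
    w[marker_idx[[types$name[k]]]] <-
      w[marker_idx[[types$name[k]]]] * types$marker_fold[k]
    w_lq <- w
    if (n_mito > 0) w_lq[mito] <- w_lq[mito] * cfg$low_quality_mito_boost
    p <- w / sum(w)
    p_lq <- w_lq / sum(w_lq)
    mean_mat <- matrix(0, cfg$n_genes, n)
    mean_mat[, !lq] <- outer(p, depth[!lq])
    if (any(lq)) mean_mat[, lq] <- outer(p_lq, depth[lq])
    if (cfg$baseline_dispersion > 0) {
      shape <- 1 / cfg$baseline_dispersion
      noise <- matrix(rgamma(length(mean_mat), shape = shape, rate = shape),
        nrow = cfg$n_genes)
      mean_mat <- mean_mat * noise
    }
    counts <- matrix(rpois(length(mean_mat), mean_mat), nrow = cfg$n_genes)
    blocks[[k]] <- counts
    truth[[k]] <- tibble(
      cell_barcode = cells,
      cell_type = types$name[k],
      lineage = types$lineage[k],
      sample_id = paste0("S", sample.int(cfg$n_samples, n, replace = TRUE)),
      intended_depth = depth,
      low_quality = lq
    )
  }
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(genes, barcodes)
  out <- list(
    matrix = methods::as(Matrix::Matrix(counts, sparse = TRUE),
      "CsparseMatrix"),
    truth = list_rbind(truth)
  )
  attr(out, "planted_markers") <- planted
  out
}

#' Label tables from simulation truth
#'
#' Convenience accessor turning a simulation's truth tibble into a label
#' table at the requested granularity.
#'
#' @param truth The `truth` tibble from [simulate_dataset()].
#' @param granularity `"cell_type"` or `"lineage"`.
#' @return A label table tibble.
#' @export
sim_labels <- function(truth, granularity = c("cell_type", "lineage")) {
  granularity <- match.arg(granularity)
  tibble(
    cell_barcode = truth$cell_barcode,
    label = truth[[granularity]],
    granularity = granularity,
    sample_id = truth$sample_id
  )
}
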