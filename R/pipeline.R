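# End-to-end driver: QC -> split -> markers -> train -> sweep -> select ->
# rescue, with per-stage seeds derived from one master seed and a
# machine-readable run manifest (paths + md5 checksums + stage logs).

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the input data; its seed is
#'   overridden by a stage seed derived from `seed`. (To run on real data,
#'   call the stage functions directly; the pipeline driver is the synthetic
#'   end-to-end harness.)
#' @param qc A [qc_thresholds()] object.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @param n_per_label,train_fraction Stratified split parameters.
#' @param markers A [marker_params()] object.
#' @param classifiers Character subset of `c("correlation", "pair_forest")`.
#' @param granularities Character subset of `c("lineage", "cell_type")`.
#' @param grid Threshold grid for the sweep.
#' @param mode Downsampling mode.
#' @param cutoff AUROC cutoff for threshold selection.
#' @param select_classifier,select_granularity Which sweep curve drives the
#'   selected threshold.
#' @param seed Master seed; every stage derives its own seed from it via
#'   [derive_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_thresholds(),
                            mito_prefix = "MT-", n_per_label = 400,
                            train_fraction = 0.5,
                            markers = marker_params(),
                            classifiers = c("correlation", "pair_forest"),
                            granularities = c("lineage", "cell_type"),
                            grid = default_threshold_grid(),
                            mode = "paper_literal", cutoff = 0.9,
                            select_classifier = "correlation",
                            select_granularity = "cell_type",
                            seed = 1L) {
  if (!length(classifiers)) abort("at least one classifier must be enabled")
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  granularities <- match.arg(granularities, several.ok = TRUE)
  if (!select_classifier %in% classifiers ||
      !select_granularity %in% granularities) {
    abort("the selection classifier/granularity must be among those enabled")
  }
  structure(
    list(sim = sim, qc = qc, mito_prefix = mito_prefix,
      n_per_label = n_per_label, train_fraction = train_fraction,
      markers = markers, classifiers = classifiers,
      granularities = granularities, grid = grid, mode = mode,
      cutoff = cutoff, select_classifier = select_classifier,
      select_granularity = select_granularity, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full threshold-optimization pipeline
#'
#' Simulates (or receives) labelled count data, applies QC, splits the
#' gold-standard cells per granularity, finds markers, trains the enabled
#' classifiers, sweeps the threshold grid, selects the minimal accurate
#' threshold, and rescues + classifies the qualifying low-depth cells. All
#' artifacts are written under `out_dir` as plain CSV/TSV/JSON and listed,
#' with md5 checksums, in `manifest.json`. Re-running with the same config
#' reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: a list with the selected threshold,
#'   per-stage cell counts, and each artifact's path and checksum.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- list()
  log <- list()
  add_artifact <- function(name, path) {
    artifacts[[name]] <<- list(
      path = basename(path),
      md5 = unname(tools::md5sum(path))
    )
  }

  # -- data --
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "sim")
  data <- simulate_dataset(sim)
  m <- data$matrix
  truth_all <- bind_rows(
    sim_labels(data$truth, "cell_type"),
    sim_labels(data$truth, "lineage")
  )
  log$n_cells <- ncol(m)
  log$n_genes <- nrow(m)

  # -- qc --
  stats <- compute_cell_stats(m, config$mito_prefix) |> apply_qc(config$qc)
  part <- table(stats$partition)
  log$n_high_quality <- as.integer(part[["high_quality"]])
  log$n_rescue_pool <- as.integer(part[["rescue_pool"]])
  log$n_excluded <- as.integer(part[["excluded"]])
  p_stats <- file.path(out_dir, "cell_stats.csv")
  readr::write_csv(stats, p_stats); add_artifact("cell_stats", p_stats)

  hq <- stats$cell_barcode[stats$partition == "high_quality"]
  if (!length(hq)) {
    abort("qc stage: no cell passes the high-quality filter; relax `qc`")
  }
  m_hq <- m[, hq, drop = FALSE]
  hq_labels <- truth_all |> filter(.data$cell_barcode %in% hq)

  # -- per-granularity: split, markers, train, sweep --
  sweeps <- list()
  select_models <- list()
  for (gran in config$granularities) {
    labs_g <- hq_labels |> filter(.data$granularity == gran)
    split <- stratified_split(labs_g, n_per_label = config$n_per_label,
      train_fraction = config$train_fraction,
      seed = derive_seed(config$seed, paste0("split_", gran)))
    m_train <- m_hq[, split$train, drop = FALSE]
    m_test <- m_hq[, split$test, drop = FALSE]
    labs_train <- labs_g |> filter(.data$cell_barcode %in% split$train)
    log[[paste0("n_train_", gran)]] <- length(split$train)
    log[[paste0("n_test_", gran)]] <- length(split$test)

    mk <- find_markers(m_train, labs_train, params = config$markers,
      seed = derive_seed(config$seed, paste0("markers_", gran)))
    p_mk <- file.path(out_dir, paste0("markers_", gran, ".tsv"))
    readr::write_tsv(as_tibble(mk), p_mk)
    add_artifact(paste0("markers_", gran), p_mk)

    models <- list()
    if ("correlation" %in% config$classifiers) {
      models$correlation <- train_correlation(m_train, labs_train)
    }
    if ("pair_forest" %in% config$classifiers) {
      models$pair_forest <- train_pair_forest(m_train, labs_train, mk,
        seed = derive_seed(config$seed, paste0("forest_", gran)))
    }
    sweeps[[gran]] <- threshold_sweep(
      m_test, labs_g, models, grid = config$grid, mode = config$mode,
      seed = derive_seed(config$seed, paste0("sweep_", gran))
    )
    # keep one selection model per granularity for rescue
    select_models[[gran]] <- models[[config$select_classifier]]
  }
  sweep <- list_rbind(map(sweeps, as_tibble))
  class(sweep) <- c("sweep_result", class(sweep))
  p_sweep <- file.path(out_dir, "sweep.csv")
  readr::write_csv(tidy(sweep), p_sweep); add_artifact("sweep", p_sweep)

  # -- select --
  t_opt <- select_threshold(sweep, cutoff = config$cutoff,
    classifier = config$select_classifier,
    granularity = config$select_granularity)
  selection <- list(
    selected_threshold = if (is.na(t_opt)) NULL else t_opt,
    cutoff = config$cutoff, classifier = config$select_classifier,
    granularity = config$select_granularity
  )
  p_sel <- file.path(out_dir, "selection.json")
  jsonlite::write_json(selection, p_sel, auto_unbox = TRUE, digits = NA,
    null = "null")
  add_artifact("selection", p_sel)

  # -- rescue --
  rescue <- NULL
  if (!is.na(t_opt) && t_opt < config$qc$min_umis) {
    rescue <- rescue_cells(
      m, stats, select_models, t_opt, hq_labels,
      initial_threshold = config$qc$min_umis,
      sample_ids = distinct(data$truth[c("cell_barcode", "sample_id")]),
      truth = truth_all
    )
    p_gain <- file.path(out_dir, "rescue_gains.csv")
    readr::write_csv(tidy(rescue), p_gain); add_artifact("rescue_gains", p_gain)
    p_lab <- file.path(out_dir, "rescued_labels.tsv")
    write_labels(rescue$rescued_labels, p_lab)
    add_artifact("rescued_labels", p_lab)
    log$n_rescued <- rescue$n_rescued
  }

  manifest <- list(
    package = "umiopt",
    schema_version = "1.0",
    seed = config$seed,
    log = log,
    selection = selection,
    artifacts = artifacts
  )
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(manifest)
}
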