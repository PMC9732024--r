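# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# tiny deterministic matrix with mito genes and named cells
toy_matrix <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 4, 1, 4),
    j = c(1, 1, 2, 2, 3, 3),
    x = c(30, 120, 5, 7, 2, 1),
    dims = c(4, 3),
    dimnames = list(c("MT-CO1", "ACTB", "CD3E", "MS4A1"),
      c("c1", "c2", "c3"))
  )
  methods::as(m, "CsparseMatrix")
}

# the default synthetic fixture + derived objects, simulated once
default_sim <- function() cached("sim", simulate_dataset(sim_config(seed = 1)))

default_qc_stats <- function() {
  cached("stats", {
    sim <- default_sim()
    apply_qc(compute_cell_stats(sim$matrix))
  })
}

# gold-standard split and correlation model at cell_type granularity
default_training <- function() {
  cached("training", {
    sim <- default_sim()
    stats <- default_qc_stats()
    labs <- sim_labels(sim$truth, "cell_type")
    hq <- stats$cell_barcode[stats$partition == "high_quality"]
    labs_hq <- labs[labs$cell_barcode %in% hq, ]
    split <- stratified_split(labs_hq, seed = 1)
    list(
      sim = sim,
      labs_hq = labs_hq,
      split = split,
      m_train = sim$matrix[, split$train],
      m_test = sim$matrix[, split$test],
      labs_train = labs_hq[labs_hq$cell_barcode %in% split$train, ],
      labs_test = labs_hq[labs_hq$cell_barcode %in% split$test, ]
    )
  })
}

default_correlation_model <- function() {
  cached("cm", {
    tr <- default_training()
    train_correlation(tr$m_train, tr$labs_train)
  })
}

default_markers <- function() {
  cached("markers", {
    tr <- default_training()
    find_markers(tr$m_train, tr$labs_train, seed = 1)
  })
}

# the full correlation sweep backing the end-to-end checks
default_sweep <- function() {
  cached("sweep", {
    tr <- default_training()
    threshold_sweep(tr$m_test, tr$labs_hq, list(default_correlation_model()),
      seed = 1)
  })
}

test_truth_vector <- function() {
  tr <- default_training()
  tr$labs_test$label[match(colnames(tr$m_test), tr$labs_test$cell_barcode)]
}

# a small, fast, well-separated fixture for classifier unit tests
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(
      n_genes = 300, n_mito_genes = 5,
      cell_types = tibble::tibble(
        name = c("T-cells", "B-cells", "fibroblasts"),
        lineage = c("immune", "immune", "stromal"),
        n_cells = 80L,
        depth_log_mean = log(3000),
        depth_log_sd = 0.3,
        marker_gene_count = 15L,
        marker_fold = 10
      ),
      low_quality_fraction = 0, seed = 42
    )
    simulate_dataset(cfg)
  })
}
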