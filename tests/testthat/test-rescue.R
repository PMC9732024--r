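rescue_setup <- function() {
  cached("rescue_setup", {
    sim <- default_sim()
    stats <- default_qc_stats()
    tr <- default_training()
    truth_both <- dplyr::bind_rows(
      sim_labels(sim$truth, "cell_type"),
      sim_labels(sim$truth, "lineage")
    )
    hq_labels <- truth_both[truth_both$cell_barcode %in%
        stats$cell_barcode[stats$partition == "high_quality"], ]
    list(sim = sim, stats = stats, model = default_correlation_model(),
      truth_both = truth_both, hq_labels = hq_labels)
  })
}

test_that("only depth-qualified rescue-pool cells are rescued", {
  fx <- rescue_setup()
  rep <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 450,
    fx$hq_labels, truth = fx$truth_both)
  pool <- fx$stats[fx$stats$partition == "rescue_pool", ]
  expect_setequal(rep$rescued_barcodes,
    pool$cell_barcode[pool$total_umis > 450])
  # excluded (mito/doublet) cells are never rescued
  excl <- fx$stats$cell_barcode[fx$stats$partition == "excluded"]
  expect_length(intersect(rep$rescued_barcodes, excl), 0)
})

test_that("gain percentages are rescued/initial and conservation holds per class", {
  fx <- rescue_setup()
  rep <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 450,
    fx$hq_labels, truth = fx$truth_both)
  g <- tidy(rep)
  with_gain <- g[g$status == "gain", ]
  expect_equal(with_gain$percent_gain,
    100 * with_gain$rescued_count / with_gain$initial_count)
  # conservation by true class: initial + rescued + still-excluded = eligible
  truth_ct <- fx$sim$truth
  stats_truth <- dplyr::inner_join(fx$stats, truth_ct, by = "cell_barcode")
  eligible <- stats_truth[stats_truth$partition != "excluded", ]
  for (ct in unique(truth_ct$cell_type)) {
    n_eligible <- sum(eligible$cell_type == ct)
    n_initial <- sum(eligible$cell_type == ct &
        eligible$partition == "high_quality")
    n_rescued <- sum(eligible$cell_type == ct &
        eligible$cell_barcode %in% rep$rescued_barcodes)
    n_still <- sum(eligible$cell_type == ct &
        eligible$partition == "rescue_pool" &
        !eligible$cell_barcode %in% rep$rescued_barcodes)
    expect_equal(n_initial + n_rescued + n_still, n_eligible)
  }
})

test_that("rescued counts are monotone in the optimized threshold", {
  fx <- rescue_setup()
  rep_450 <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 450,
    fx$hq_labels)
  rep_250 <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 250,
    fx$hq_labels)
  expect_gte(rep_250$n_rescued, rep_450$n_rescued)
  merged <- dplyr::full_join(tidy(rep_450), tidy(rep_250),
    by = c("granularity", "label"), suffix = c("_450", "_250"))
  merged[is.na(merged)] <- 0L
  expect_true(all(merged$rescued_count_250 >= merged$rescued_count_450))
})

test_that("rescued cells carry exactly one model-label call per granularity", {
  fx <- rescue_setup()
  rep <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 450,
    fx$hq_labels)
  rl <- rep$rescued_labels
  expect_true(all(rl$label %in% unique(fx$model$labels)))
  per_cell <- dplyr::count(rl, cell_barcode, granularity)
  expect_true(all(per_cell$n == 1))
  expect_setequal(unique(rl$cell_barcode), rep$rescued_barcodes)
})

test_that("per-sample composition frequencies sum to one before and after", {
  fx <- rescue_setup()
  rep <- rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 450,
    fx$hq_labels,
    sample_ids = dplyr::distinct(fx$sim$truth[c("cell_barcode", "sample_id")]))
  sums <- rep$composition |>
    dplyr::summarise(s = sum(frequency),
      .by = c(sample_id, granularity, when))
  expect_equal(sums$s, rep(1, nrow(sums)))
})

test_that("degenerate rescue configurations behave", {
  fx <- rescue_setup()
  expect_error(rescue_cells(fx$sim$matrix, fx$stats, list(fx$model), 1500,
    fx$hq_labels), "below the initial")
  # an empty pool still yields a valid all-zero report
  stats_hq_only <- fx$stats[fx$stats$partition != "rescue_pool", ]
  rep <- rescue_cells(fx$sim$matrix, stats_hq_only, list(fx$model), 450,
    fx$hq_labels)
  expect_equal(rep$n_rescued, 0L)
  expect_true(all(tidy(rep)$rescued_count == 0))
})
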