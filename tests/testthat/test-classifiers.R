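# two labels with disjoint 10-gene signatures on a flat background
signature_fixture <- function() {
  genes <- c(paste0("sigA", 1:10), paste0("sigB", 1:10), paste0("bg", 1:5))
  n <- 12L
  m <- matrix(1, length(genes), 2 * n,
    dimnames = list(genes, sprintf("c%02d", seq_len(2 * n))))
  m[paste0("sigA", 1:10), seq_len(n)] <- 20
  m[paste0("sigB", 1:10), n + seq_len(n)] <- 20
  labs <- tibble::tibble(
    cell_barcode = colnames(m),
    label = rep(c("A", "B"), each = n),
    granularity = "cell_type"
  )
  list(m = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
    labs = labs)
}

test_that("correlation training collects the pairwise median-difference genes", {
  fx <- signature_fixture()
  cm <- train_correlation(fx$m, fx$labs, top_n = 10)
  # brute-force oracle: rank genes by difference of per-label medians
  med <- function(lab) apply(as.matrix(fx$m[, fx$labs$label == lab]), 1, median)
  d <- med("A") - med("B")
  topA <- names(sort(d, decreasing = TRUE))[1:10]
  topB <- names(sort(-d, decreasing = TRUE))[1:10]
  expect_setequal(cm$marker_genes, union(topA, topB))
  expect_setequal(cm$marker_genes, c(paste0("sigA", 1:10), paste0("sigB", 1:10)))
  # determinism
  cm2 <- train_correlation(fx$m, fx$labs, top_n = 10)
  expect_identical(cm$marker_genes, cm2$marker_genes)
})

test_that("degenerate correlation configurations are rejected", {
  fx <- signature_fixture()
  expect_error(train_correlation(fx$m, fx$labs, top_n = 0), "at least 1")
  one <- fx$labs; one$label <- "A"
  expect_error(train_correlation(fx$m, one), "at least 2")
})

test_that("correlation scores equal the quantile of per-reference Spearman correlations", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  # 5 reference cells per label, a handful of test cells
  set.seed(1)
  ref_cells <- unlist(lapply(split(labs$cell_barcode, labs$label), head, 5))
  test_cells <- setdiff(labs$cell_barcode, ref_cells)[1:8]
  labs_ref <- labs[labs$cell_barcode %in% ref_cells, ]
  cm <- train_correlation(sim$matrix[, ref_cells], labs_ref)
  sm <- predict_correlation(cm, sim$matrix[, test_cells])
  # oracle: direct enumeration with cor(method = "spearman")
  g <- cm$marker_genes
  for (cell in test_cells[1:3]) {
    for (lab in unique(labs_ref$label)) {
      refs <- labs_ref$cell_barcode[labs_ref$label == lab]
      cors <- vapply(refs, function(r) {
        cor(as.numeric(sim$matrix[g, cell]), as.numeric(sim$matrix[g, r]),
          method = "spearman")
      }, numeric(1))
      expect_equal(sm$scores[cell, lab],
        unname(quantile(cors, 0.8, names = FALSE)))
    }
  }
})

test_that("a test cell identical to a reference correlates perfectly and calls its label", {
  fx <- signature_fixture()
  cm <- train_correlation(fx$m, fx$labs)
  sm <- predict_correlation(cm, fx$m[, "c01", drop = FALSE])
  expect_equal(unname(sm$call["c01"]), "A")
  expect_equal(unname(sm$scores["c01", "A"]), 1.0)
})

test_that("correlation scores are invariant to depth scaling", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  cm <- train_correlation(sim$matrix[, 1:100], labs[1:100, ])
  probe <- sim$matrix[, 101:105]
  sm1 <- predict_correlation(cm, probe)
  sm2 <- predict_correlation(cm, probe * 7)
  expect_equal(sm1$scores, sm2$scores)
  expect_true(all(sm1$scores >= -1 & sm1$scores <= 1))
})

test_that("zero-variance cells are flagged and called by the tie rule", {
  fx <- signature_fixture()
  cm <- train_correlation(fx$m, fx$labs)
  empty <- fx$m[, 1, drop = FALSE] * 0
  colnames(empty) <- "void"
  sm <- predict_correlation(cm, Matrix::drop0(empty))
  expect_true(sm$flagged["void"])
  expect_true(all(sm$scores["void", ] == 0))
  expect_equal(unname(sm$call["void"]), "A")  # lexicographically smallest
})

test_that("pair features implement the strict-greater indicator", {
  X <- matrix(c(5, 2, 3, 2, 5, 3), nrow = 2, byrow = TRUE,
    dimnames = list(c("gi", "gj"), c("x", "y", "z")))
  pairs <- tibble::tibble(gene_i = "gi", gene_j = "gj")
  feat <- umiopt:::pair_feature_matrix(X, pairs)
  expect_equal(as.numeric(feat), c(1, 0, 0))  # (5,2)->1, (2,5)->0, (3,3)->0
})

test_that("the gene-pair forest separates a separable fixture and is deterministic", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  mk <- find_markers(sim$matrix, labs, seed = 2)
  pf <- train_pair_forest(sim$matrix, labs, mk, n_trees = 300, seed = 5)
  pf2 <- train_pair_forest(sim$matrix, labs, mk, n_trees = 300, seed = 5)
  expect_identical(pf$pair_features, pf2$pair_features)
  sm <- predict_pair_forest(pf, sim$matrix)
  truth <- labs$label[match(rownames(sm$scores), labs$cell_barcode)]
  expect_gte(mean(sm$call == truth), 0.99)
  # vote fractions are a distribution over labels + rand
  expect_true(all(sm$scores >= 0 & sm$scores <= 1))
  expect_equal(unname(rowSums(sm$scores)), rep(1, nrow(sm$scores)))
})

test_that("shuffled cells score higher on the rand class than real cells", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  mk <- find_markers(sim$matrix, labs, seed = 2)
  pf <- train_pair_forest(sim$matrix, labs, mk, n_trees = 300, seed = 5)
  m <- as.matrix(sim$matrix[, 1:40])
  set.seed(8)
  shuffled <- apply(m, 2, sample)  # per-cell gene shuffle destroys structure
  rownames(shuffled) <- sample(rownames(m))
  colnames(shuffled) <- paste0("shuf", seq_len(ncol(shuffled)))
  sm_real <- predict_pair_forest(pf, sim$matrix[, 1:40])
  sm_shuf <- predict_pair_forest(pf,
    methods::as(Matrix::Matrix(shuffled, sparse = TRUE), "CsparseMatrix"))
  expect_gt(mean(sm_shuf$scores[, "rand"]), mean(sm_real$scores[, "rand"]))
})

test_that("an all-zero cell gets the deterministic constant-profile score", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  mk <- find_markers(sim$matrix, labs, seed = 2)
  pf <- train_pair_forest(sim$matrix, labs, mk, n_trees = 200, seed = 5)
  z <- sim$matrix[, 1:2] * 0
  colnames(z) <- c("z1", "z2")
  sm <- predict_pair_forest(pf, Matrix::drop0(z))
  expect_equal(sm$scores["z1", ], sm$scores["z2", ])
})
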