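test_that("stratified splitting samples per label and partitions 1:1", {
  labs <- tibble::tibble(
    cell_barcode = sprintf("c%04d", 1:3000),
    label = rep(c("A", "B", "C"), each = 1000),
    granularity = "cell_type"
  )
  sp <- stratified_split(labs, seed = 3)
  expect_length(sp$train, 600)  # 200 per label
  expect_length(sp$test, 600)
  expect_length(intersect(sp$train, sp$test), 0)
  per_label <- table(labs$label[match(sp$train, labs$cell_barcode)])
  expect_true(all(per_label == 200))
  # min rule: a label with fewer cells than n_per_label uses all of them
  small <- labs[c(1:100, 1001:2000), ]
  sp2 <- stratified_split(small, seed = 3)
  a_cells <- small$cell_barcode[small$label == "A"]
  expect_equal(sum(sp2$train %in% a_cells), 50)
  expect_equal(sum(sp2$test %in% a_cells), 50)
  # determinism
  sp3 <- stratified_split(labs, seed = 3)
  expect_identical(sp, sp3)
  expect_error(stratified_split(labs[1, ]), "fewer than 2")
})

test_that("confusion matrices count truth-by-call and conserve totals", {
  truth <- c("A", "A", "B", "B", "C")
  perfect <- confusion_matrix(truth, truth)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(diag(perfect), c(A = 2L, B = 2L, C = 1L))
  collapsed <- confusion_matrix(truth, rep("A", 5))
  expect_equal(sum(collapsed[, "A"]), 5L)
  expect_equal(sum(collapsed), length(truth))
  expect_error(confusion_matrix(truth, truth[-1]), "same length")
})

test_that("binary AUROC follows the rank-sum definition", {
  expect_equal(binary_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(binary_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(binary_auc(c(0.8, 0.4, 0.6, 0.5, 0.3), c(1, 1, 1, 0, 0)), 5 / 6)
  expect_error(binary_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

# independent oracle: enumerate every positive-negative pair, ties count 1/2
brute_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("binary AUROC equals all-pairs enumeration on random tied instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(binary_auc(scores, truth), brute_auc(scores, truth),
      tolerance = 1e-12)
  }
})

test_that("the pairwise-averaged multiclass AUROC reduces and enumerates correctly", {
  # 2-class reduction: with complementary score columns the pairwise measure
  # equals the binary AUROC of the positive-class column
  set.seed(7)
  pos <- runif(20)
  sc <- cbind(A = pos, B = 1 - pos)
  truth2 <- rep(c("A", "B"), each = 10)
  expect_equal(multiclass_auc(sc, truth2, "hand_till"),
    binary_auc(sc[, "A"], truth2 == "A"))
  # one-hot scores classify perfectly under both methods
  truth3 <- rep(c("A", "B", "C"), each = 3)
  onehot <- diag(3)[rep(1:3, each = 3), ]
  colnames(onehot) <- c("A", "B", "C")
  expect_equal(multiclass_auc(onehot, truth3, "hand_till"), 1)
  expect_equal(multiclass_auc(onehot, truth3, "macro_ovr"), 1)
  # 9-cell toy vs brute-force pairwise averaging
  set.seed(8)
  sc3 <- matrix(runif(27), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  classes <- c("A", "B", "C")
  total <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    sub <- truth3 %in% classes[c(i, j)]
    aij <- brute_auc(sc3[sub, classes[i]], truth3[sub] == classes[i])
    aji <- brute_auc(sc3[sub, classes[j]], truth3[sub] == classes[j])
    total <- total + (aij + aji) / 2
  }
  expect_equal(multiclass_auc(sc3, truth3, "hand_till"), total * 2 / (3 * 2))
  # symmetric under class relabelling
  perm <- c("C", "A", "B")
  sc_perm <- sc3[, perm]
  truth_perm <- truth3
  expect_equal(multiclass_auc(sc_perm, truth_perm, "hand_till"),
    multiclass_auc(sc3, truth3, "hand_till"))
  expect_error(multiclass_auc(sc3[, 1:2], truth3), "without a score column")
})

test_that("threshold selection returns the smallest qualifying grid value", {
  sweep <- tibble::tibble(
    threshold = c(NA, 350L, 450L, 1500L),
    classifier = "correlation", granularity = "cell_type",
    auroc = c(0.99, 0.89, 0.92, 0.95)
  )
  class(sweep) <- c("sweep_result", class(sweep))
  expect_equal(select_threshold(sweep, 0.9), 450L)
  expect_equal(select_threshold(sweep, 0.7), 350L)
  expect_true(is.na(select_threshold(sweep, 0.99)))
  # monotone in the cutoff
  cuts <- seq(0.5, 1, by = 0.05)
  sel <- vapply(cuts, function(ct) {
    s <- select_threshold(sweep, ct)
    if (is.na(s)) Inf else as.double(s)
  }, numeric(1))
  expect_true(all(diff(sel) >= 0))
})

test_that("the sweep records a control row, hits 0.5 at target 0, and is reproducible", {
  sim <- small_sim()
  labs <- sim_labels(sim$truth)
  sp <- stratified_split(labs, n_per_label = 60, seed = 2)
  cm <- train_correlation(sim$matrix[, sp$train],
    labs[labs$cell_barcode %in% sp$train, ])
  m_test <- sim$matrix[, sp$test]
  grid <- c(0L, 200L, 2000L)
  sw <- threshold_sweep(m_test, labs, list(cm), grid = grid, seed = 6)
  expect_equal(nrow(sw), length(grid) + 1L)
  expect_equal(sw$auroc[sw$threshold %in% 0L], 0.5)
  # the untransformed control equals direct prediction
  truth <- labs$label[match(colnames(m_test), labs$cell_barcode)]
  direct <- multiclass_auc(predict_correlation(cm, m_test), truth)
  expect_equal(sw$auroc[is.na(sw$threshold)], direct)
  # deeper targets classify at least as well as shallow ones here
  expect_gte(sw$auroc[sw$threshold %in% 2000L], sw$auroc[sw$threshold %in% 200L])
  sw2 <- threshold_sweep(m_test, labs, list(cm), grid = grid, seed = 6)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})
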