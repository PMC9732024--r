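# Stratified splitting, confusion matrices, binary and multiclass AUROC
# (Hand & Till pairwise averaging and macro one-vs-rest), the depth-threshold
# sweep, and minimal-threshold selection.

#' Stratified per-label train/test split
#'
#' Samples up to `n_per_label` cells per label without replacement, then
#' splits each label's sample into train and test (`floor(train_fraction *
#' n)` cells to train).
#'
#' @param labels Label table (one granularity).
#' @param n_per_label Cells sampled per label (default 400).
#' @param train_fraction Fraction of each label's sample going to train.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test` of cell barcodes
#'   (disjoint).
#' @export
stratified_split <- function(labels, n_per_label = 400, train_fraction = 0.5,
                             seed = 1L) {
  labels <- validate_labels(labels)
  stopifnot(train_fraction > 0, train_fraction < 1, n_per_label >= 2)
  groups <- split(labels$cell_barcode, labels$label)
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    abort(sprintf("label(s) with fewer than 2 cells: %s",
      paste(small, collapse = ", ")))
  }
  train <- character(); test <- character()
  for (L in sort(names(groups))) {
    set.seed(derive_seed(seed, L))
    pool <- sample(groups[[L]], min(n_per_label, length(groups[[L]])))
    n_train <- floor(train_fraction * length(pool))
    train <- c(train, pool[seq_len(n_train)])
    test <- c(test, pool[-seq_len(n_train)])
  }
  list(train = train, test = test)
}

#' Confusion matrix of true vs called labels
#'
#' @param truth,calls Equal-length label vectors.
#' @return An integer matrix, rows = truth, columns = calls, over the sorted
#'   union of labels.
#' @export
confusion_matrix <- function(truth, calls) {
  if (length(truth) != length(calls)) {
    abort("`truth` and `calls` must have the same length")
  }
  levels <- sort(union(unique(truth), unique(calls)))
  tab <- table(factor(truth, levels), factor(calls, levels))
  mat <- matrix(as.integer(tab), nrow = length(levels),
    dimnames = list(truth = levels, call = levels))
  mat
}

#' Binary AUROC by the rank-sum (Mann-Whitney) identity
#'
#' Equals `P(score_pos > score_neg) + 0.5 P(tie)` over all positive-negative
#' pairs.
#'
#' @param scores Numeric score vector.
#' @param truth Logical (or coercible 0/1) vector; `TRUE` = positive.
#' @return AUROC in \[0, 1\].
#' @export
binary_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("length mismatch")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute an AUROC")
  }
  r <- rank(scores)  # average ties
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multiclass AUROC from a score matrix
#'
#' `"hand_till"` (default) averages, over all unordered class pairs, the mean
#' of the two within-pair one-vs-one AUROCs computed from each class's score
#' column, scaled by `2 / (c (c - 1))`; `"macro_ovr"` averages the
#' one-vs-rest binary AUROC of each class's score column. With two classes
#' both reduce to [binary_auc()].
#'
#' @param scores A `score_matrix` or a cells x labels numeric matrix with
#'   label colnames.
#' @param truth Label vector aligned with the score rows.
#' @param method `"hand_till"` or `"macro_ovr"`.
#' @return AUROC in \[0, 1\].
#' @export
multiclass_auc <- function(scores, truth, method = c("hand_till", "macro_ovr")) {
  method <- match.arg(method)
  if (inherits(scores, "score_matrix")) scores <- scores$scores
  classes <- sort(unique(truth))
  if (length(classes) < 2) abort("need at least 2 classes in `truth`")
  missing <- setdiff(classes, colnames(scores))
  if (length(missing)) {
    abort(sprintf("class(es) in `truth` without a score column: %s",
      paste(missing, collapse = ", ")))
  }
  if (length(truth) != nrow(scores)) abort("length mismatch")
  if (method == "macro_ovr") {
    return(mean(map_dbl(classes, function(k) {
      binary_auc(scores[, k], truth == k)
    })))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  total <- sum(map_dbl(pairs, function(p) {
    sub <- truth %in% p
    a_given_b <- binary_auc(scores[sub, p[1]], truth[sub] == p[1])
    b_given_a <- binary_auc(scores[sub, p[2]], truth[sub] == p[2])
    (a_given_b + b_given_a) / 2
  }))
  c <- length(classes)
  2 / (c * (c - 1)) * total
}

#' The default UMI target grid
#'
#' @return The ordered integer grid of target depths used by the sweep:
#'   0--4000 UMIs at increasing spacing.
#' @export
default_threshold_grid <- function() {
  c(0L, 50L, 100L, 150L, 200L, 250L, 300L, 350L, 400L, 450L, 500L, 600L,
    700L, 800L, 900L, 1000L, 1500L, 2000L, 3000L, 4000L)
}

#' Sweep classification accuracy across a grid of target depths
#'
#' For every grid target the test matrix is Poisson-downsampled (one draw per
#' grid point, seeded by `derive_seed(seed, target)` so grid points are
#' independent but reproducible), every model scores the transformed cells,
#' and the realized depth statistics, the multiclass AUROC and the confusion
#' matrix are recorded. An untransformed control row (`threshold = NA`) is
#' always included.
#'
#' @param m_test Genes x cells count matrix of held-out cells.
#' @param truth Label table covering the test cells at every granularity the
#'   models use.
#' @param models A list of trained `correlation_model` /
#'   `pair_forest_model` objects (each knows its classifier and granularity).
#' @param grid Integer vector of target depths; default
#'   [default_threshold_grid()].
#' @param mode Downsampling mode passed to [downsample_matrix()].
#' @param auc_method Multiclass AUROC method, see [multiclass_auc()].
#' @param seed Integer base seed.
#' @return A tibble of class `sweep_result`: one row per (threshold,
#'   classifier, granularity) with realized `mean_umis`, `median_umis`,
#'   `mean_genes`, `median_genes`, `auroc` and a `confusion` list-column.
#' @export
threshold_sweep <- function(m_test, truth, models,
                            grid = default_threshold_grid(),
                            mode = "paper_literal",
                            auc_method = "hand_till", seed = 1L) {
  m_test <- as_count_matrix(m_test)
  truth <- validate_labels(truth)
  if (is.null(names(models))) {
    names(models) <- map_chr(models, function(mod) {
      paste(attr(mod, "classifier"), attr(mod, "granularity"), sep = "_")
    })
  }
  stopifnot(all(diff(grid) > 0), all(grid >= 0))
  evaluate_at <- function(m_at, threshold) {
    totals <- cell_totals(m_at)
    ngenes <- cells_n_genes(m_at)
    rows <- map(models, function(mod) {
      gran <- attr(mod, "granularity")
      tr <- truth[truth$granularity == gran, ]
      tr <- tr[match(colnames(m_at), tr$cell_barcode), ]
      if (anyNA(tr$label)) abort(sprintf(
        "truth labels at granularity '%s' do not cover all test cells", gran))
      sm <- predict_cells(mod, m_at)
      tibble(
        threshold = threshold,
        classifier = attr(mod, "classifier"),
        granularity = gran,
        mean_umis = mean(totals), median_umis = stats::median(totals),
        mean_genes = mean(ngenes), median_genes = stats::median(ngenes),
        auroc = multiclass_auc(sm, tr$label, method = auc_method),
        confusion = list(confusion_matrix(tr$label, unname(sm$call)))
      )
    })
    list_rbind(rows)
  }
  out <- list(evaluate_at(m_test, NA_integer_))
  for (target in grid) {
    m_at <- downsample_matrix(m_test, target, mode = mode,
      seed = derive_seed(seed, target + 1L))
    out <- c(out, list(evaluate_at(m_at, as.integer(target))))
  }
  res <- list_rbind(out)
  class(res) <- c("sweep_result", class(res))
  res
}

predict_cells <- function(model, m) {
  switch(attr(model, "classifier"),
    correlation = predict_correlation(model, m),
    pair_forest = predict_pair_forest(model, m),
    abort("unknown classifier type")
  )
}

#' Select the minimal accurate threshold from a sweep
#'
#' The smallest grid threshold whose AUROC reaches `cutoff` for the stated
#' classifier and granularity (the untransformed control row is ignored).
#'
#' @param sweep A `sweep_result`.
#' @param cutoff AUROC cutoff (0.9 by default; 0.7 suits harder datasets).
#' @param classifier,granularity Which sweep rows to use.
#' @param strict If `FALSE` (default) a threshold qualifies when
#'   `auroc >= cutoff`; if `TRUE`, only when strictly above.
#' @return The selected integer threshold, or `NA` if no grid point
#'   qualifies.
#' @export
select_threshold <- function(sweep, cutoff = 0.9, classifier = "correlation",
                             granularity = "cell_type", strict = FALSE) {
  rows <- sweep |>
    filter(.data$classifier == !!classifier,
      .data$granularity == !!granularity, !is.na(.data$threshold)) |>
    arrange(.data$threshold)
  if (!nrow(rows)) abort("no sweep rows match the requested classifier/granularity")
  ok <- if (strict) rows$auroc > cutoff else rows$auroc >= cutoff
  if (!any(ok)) return(NA_integer_)
  as.integer(rows$threshold[which(ok)[1]])
}

#' @export
glance.sweep_result <- function(x, ...) {
  x |>
    filter(!is.na(.data$threshold)) |>
    group_by(.data$classifier, .data$granularity) |>
    summarise(
      n_thresholds = n(),
      max_auroc = max(.data$auroc),
      min_auroc = min(.data$auroc),
      .groups = "drop"
    )
}

#' @export
tidy.sweep_result <- function(x, ...) {
  as_tibble(x) |> select(-"confusion")
}
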