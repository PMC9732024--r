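# Gene-pair random-forest classifier. Features are binary top-pair
# indicators [count_i > count_j] (ties score 0 — relevant because
# downsampling creates many zeros), built from the per-label top marker
# genes; synthetic per-gene-shuffled "rand" profiles give the forest an
# explicit background class, reported as a confidence flag rather than a
# call.

#' Train the gene-pair random forest
#'
#' Restricts the matrix to the `top_genes_per_label` best markers of each
#' label (by descending log fold change in `markers`); scores every ordered
#' candidate gene pair (i, j) by how discriminative the indicator
#' `count_i > count_j` is for the label (absolute difference of the
#' indicator's mean inside vs outside the label) and keeps the
#' `top_gene_pairs` best per label; appends `n_rand` per-gene-shuffled
#' background profiles per label, labelled `"rand"`; then trains a
#' probability random forest with `n_trees` trees on the binary pair-feature
#' matrix.
#'
#' @param m Genes x cells raw count matrix of the training cells.
#' @param labels Label table covering the training cells (one granularity).
#' @param markers A `marker_set` from [find_markers()] on the same labels.
#' @param top_genes_per_label,top_gene_pairs,n_rand,n_trees Training
#'   parameters (defaults 100, 200, 50, 1000).
#' @param seed Integer seed.
#' @return An object of class `pair_forest_model`.
#' @export
train_pair_forest <- function(m, labels, markers, top_genes_per_label = 100,
                              top_gene_pairs = 200, n_rand = 50,
                              n_trees = 1000, seed = 1L) {
  m <- as_count_matrix(m)
  labels <- validate_labels(labels)
  labels <- labels[labels$cell_barcode %in% colnames(m), ]
  lab_vec <- setNames(labels$label, labels$cell_barcode)
  labs <- sort(unique(lab_vec))
  if ("rand" %in% labs) abort("'rand' is a reserved label name")
  missing_markers <- setdiff(labs, unique(markers$label))
  if (length(missing_markers)) {
    abort(sprintf("no markers for label(s): %s",
      paste(missing_markers, collapse = ", ")))
  }
  top_by_label <- markers |>
    filter(.data$label %in% labs, .data$gene %in% rownames(m)) |>
    group_by(.data$label) |>
    arrange(desc(.data$log_fc), .by_group = TRUE) |>
    slice_head(n = top_genes_per_label) |>
    ungroup()
  universe <- unique(top_by_label$gene)
  X <- as.matrix(m[universe, names(lab_vec), drop = FALSE])

  set.seed(derive_seed(seed, "pair_features"))
  pair_features <- select_pair_features(X, lab_vec, top_by_label,
    top_gene_pairs)

  # background profiles: per-gene independent resampling within each label
  rand_list <- map(labs, function(L) {
    cols <- X[, names(lab_vec)[lab_vec == L], drop = FALSE]
    set.seed(derive_seed(seed, paste0("rand_", L)))
    vapply(seq_len(n_rand), function(k) {
      apply(cols, 1, function(v) v[sample.int(length(v), 1)])
    }, numeric(nrow(cols)))
  })
  rand_mat <- do.call(cbind, rand_list)
  colnames(rand_mat) <- paste0("rand_", seq_len(ncol(rand_mat)))

  feat_train <- pair_feature_matrix(cbind(X, rand_mat), pair_features)
  y <- factor(c(lab_vec, rep("rand", ncol(rand_mat))),
    levels = c(labs, "rand"))
  forest <- ranger::ranger(
    x = feat_train, y = y, num.trees = n_trees, probability = TRUE,
    seed = derive_seed(seed, "forest"), num.threads = 1
  )
  structure(
    list(labels = labs, pair_features = pair_features, forest = forest,
      params = list(top_genes_per_label = top_genes_per_label,
        top_gene_pairs = top_gene_pairs, n_rand = n_rand,
        n_trees = n_trees)),
    class = "pair_forest_model",
    classifier = "pair_forest",
    granularity = unique(labels$granularity)
  )
}

# score ordered pairs (i from the label's top genes, j from the whole
# universe) by |mean indicator in label - mean indicator outside|
select_pair_features <- function(X, lab_vec, top_by_label, top_gene_pairs) {
  universe <- rownames(X)
  labs <- sort(unique(lab_vec))
  feats <- list()
  for (L in labs) {
    own <- top_by_label$gene[top_by_label$label == L]
    in_cols <- lab_vec == L
    cand_i <- rep(own, each = length(universe))
    cand_j <- rep(universe, times = length(own))
    keep <- cand_i != cand_j
    cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
    score <- numeric(length(cand_i))
    chunk <- 20000L
    for (s in seq(1L, length(cand_i), by = chunk)) {
      e <- min(s + chunk - 1L, length(cand_i))
      ind <- X[cand_i[s:e], , drop = FALSE] > X[cand_j[s:e], , drop = FALSE]
      score[s:e] <- abs(rowMeans(ind[, in_cols, drop = FALSE]) -
          rowMeans(ind[, !in_cols, drop = FALSE]))
    }
    ord <- order(score, decreasing = TRUE)
    n_keep <- min(top_gene_pairs, length(ord))
    if (n_keep < top_gene_pairs) {
      warn(sprintf("label '%s': only %d candidate pairs available", L, n_keep))
    }
    feats[[L]] <- tibble(gene_i = cand_i[ord[seq_len(n_keep)]],
      gene_j = cand_j[ord[seq_len(n_keep)]])
  }
  distinct(list_rbind(feats))
}

# cells x pairs binary feature matrix; X is genes x cells, missing genes -> 0
pair_feature_matrix <- function(X, pairs) {
  get_rows <- function(g) {
    out <- matrix(0, nrow = length(g), ncol = ncol(X))
    hit <- g %in% rownames(X)
    out[hit, ] <- X[g[hit], , drop = FALSE]
    out
  }
  a <- get_rows(pairs$gene_i)
  b <- get_rows(pairs$gene_j)
  feat <- Matrix::t(a > b) * 1  # cells x pairs
  feat <- as.matrix(feat)
  colnames(feat) <- paste0(pairs$gene_i, ">", pairs$gene_j)
  rownames(feat) <- colnames(X)
  feat
}

#' Score cells with the gene-pair random forest
#'
#' Builds the model's binary pair features on the test cells (genes missing
#' from the test matrix count as 0) and returns the forest's per-label vote
#' fractions; the hard call is the argmax over the real labels, while the
#' `"rand"` background score is kept as a confidence column.
#'
#' @param model A `pair_forest_model`.
#' @param m_test Genes x cells count matrix of cells to classify.
#' @return A `score_matrix` object; vote fractions sum to 1 per cell.
#' @export
predict_pair_forest <- function(model, m_test) {
  stopifnot(inherits(model, "pair_forest_model"))
  m_test <- as_count_matrix(m_test)
  genes <- unique(c(model$pair_features$gene_i, model$pair_features$gene_j))
  common <- intersect(genes, rownames(m_test))
  X <- matrix(0, nrow = length(genes), ncol = ncol(m_test),
    dimnames = list(genes, colnames(m_test)))
  X[common, ] <- as.matrix(m_test[common, , drop = FALSE])
  feat <- pair_feature_matrix(X, model$pair_features)
  pred <- stats::predict(model$forest, data = feat, num.threads = 1)
  scores <- pred$predictions
  rownames(scores) <- colnames(m_test)
  new_score_matrix(scores, real_labels = model$labels,
    classifier = "pair_forest", granularity = attr(model, "granularity"))
}

#' @export
glance.pair_forest_model <- function(x, ...) {
  tibble(
    n_labels = length(x$labels),
    n_pair_features = nrow(x$pair_features),
    n_trees = x$params$n_trees,
    n_rand = x$params$n_rand,
    oob_error = x$forest$prediction.error,
    granularity = attr(x, "granularity")
  )
}
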