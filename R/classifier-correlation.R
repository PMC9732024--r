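# Spearman-correlation reference classifier. Trained on raw UMI counts over
# all genes; prediction correlates each unknown cell with every reference
# cell over a compact pairwise-discriminative gene set, and a label's score
# is an upper quantile of the correlations to that label's reference cells.
# Spearman makes the score invariant to any monotone per-cell scaling, so
# depth changes that preserve ranks do not move the scores.

#' Train the correlation reference classifier
#'
#' Stores the (raw count) reference cells and their labels, and builds the
#' discriminative gene set: for every ordered pair of labels (A, B), the
#' `top_n` genes with the largest difference of per-label median expression
#' (median in A minus median in B); the union over all ordered pairs is kept.
#'
#' @param m Genes x cells raw count matrix of the training cells.
#' @param labels Label table covering the training cells (one granularity).
#' @param top_n Genes kept per ordered label pair.
#' @param score_quantile Quantile of per-reference-cell correlations used as
#'   a label's score at prediction time.
#' @return An object of class `correlation_model`.
#' @export
train_correlation <- function(m, labels, top_n = 10, score_quantile = 0.8) {
  m <- as_count_matrix(m)
  labels <- validate_labels(labels)
  labels <- labels[labels$cell_barcode %in% colnames(m), ]
  if (top_n < 1) abort("`top_n` must be at least 1 (empty feature space)")
  if (score_quantile <= 0 || score_quantile > 1) {
    abort("`score_quantile` must be in (0, 1]")
  }
  lab_vec <- setNames(labels$label, labels$cell_barcode)
  labs <- sort(unique(lab_vec))
  if (length(labs) < 2) abort("need at least 2 labels to train a classifier")
  med <- vapply(labs, function(L) {
    cols <- names(lab_vec)[lab_vec == L]
    apply(as.matrix(m[, cols, drop = FALSE]), 1, stats::median)
  }, numeric(nrow(m)))
  marker_genes <- character()
  for (a in labs) {
    for (b in setdiff(labs, a)) {
      d <- med[, a] - med[, b]
      top <- rownames(m)[order(d, decreasing = TRUE)[seq_len(min(top_n, nrow(m)))]]
      marker_genes <- union(marker_genes, top)
    }
  }
  structure(
    list(
      reference = m[marker_genes, names(lab_vec), drop = FALSE],
      labels = lab_vec,
      marker_genes = marker_genes,
      score_quantile = score_quantile
    ),
    class = "correlation_model",
    classifier = "correlation",
    granularity = unique(labels$granularity)
  )
}

#' Score cells with the correlation classifier
#'
#' Each test cell is Spearman-correlated (average-rank ties) with every
#' reference cell over the model's discriminative genes (genes absent from
#' the test matrix count as 0); a label's score is the model's quantile of
#' the correlations to that label's reference cells, and the call is the
#' argmax. Cells with zero variance over the discriminative genes (for
#' example all-zero cells) get score 0 for every label, are called as the
#' lexicographically smallest label, and are flagged.
#'
#' @param model A `correlation_model`.
#' @param m_test Genes x cells count matrix of cells to classify.
#' @return A `score_matrix` object; see [tidy.score_matrix()].
#' @export
predict_correlation <- function(model, m_test) {
  stopifnot(inherits(model, "correlation_model"))
  m_test <- as_count_matrix(m_test)
  genes <- model$marker_genes
  if (length(intersect(genes, rownames(m_test))) < 2) {
    abort("test matrix shares fewer than 2 genes with the model's gene set")
  }
  test <- matrix(0, nrow = length(genes), ncol = ncol(m_test),
    dimnames = list(genes, colnames(m_test)))
  common <- intersect(genes, rownames(m_test))
  test[common, ] <- as.matrix(m_test[common, , drop = FALSE])
  ref <- as.matrix(model$reference[genes, , drop = FALSE])

  rank_cols <- function(x) apply(x, 2, rank)  # average ties
  rt <- rank_cols(test)
  rr <- rank_cols(ref)
  cors <- suppressWarnings(stats::cor(rt, rr))  # test cells x ref cells
  degenerate <- apply(rt, 2, function(r) max(r) == min(r))
  cors[!is.finite(cors)] <- 0
  labs <- sort(unique(model$labels))
  scores <- vapply(labs, function(L) {
    cols <- names(model$labels)[model$labels == L]
    apply(cors[, cols, drop = FALSE], 1, function(v) {
      stats::quantile(v, model$score_quantile, names = FALSE, type = 7)
    })
  }, numeric(ncol(m_test)))
  if (ncol(m_test) == 1L) scores <- matrix(scores, nrow = 1,
    dimnames = list(colnames(m_test), labs))
  scores[degenerate | !is.finite(rowSums(scores)), ] <- 0
  rownames(scores) <- colnames(m_test)
  new_score_matrix(scores, flagged = degenerate,
    classifier = "correlation", granularity = attr(model, "granularity"))
}

# ---- shared score container ----

new_score_matrix <- function(scores, flagged = NULL, real_labels = NULL,
                             classifier = NA_character_,
                             granularity = NA_character_) {
  real_labels <- real_labels %||% colnames(scores)
  call <- argmax_label(scores[, real_labels, drop = FALSE])
  structure(
    list(
      scores = scores,
      call = setNames(call, rownames(scores)),
      flagged = setNames(flagged %||% rep(FALSE, nrow(scores)),
        rownames(scores)),
      real_labels = real_labels
    ),
    class = "score_matrix",
    classifier = classifier,
    granularity = granularity
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "<score_matrix> %d cells x %d labels (%s, %s); %d flagged\n",
    nrow(x$scores), length(x$real_labels),
    attr(x, "classifier"), attr(x, "granularity"), sum(x$flagged)
  ))
  invisible(x)
}

#' Tidy a score matrix into one row per (cell, label)
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `cell_barcode`, `label`, `score`, `call`
#'   (the cell's hard call), `flagged`.
#' @export
tidy.score_matrix <- function(x, ...) {
  as_tibble(x$scores, rownames = "cell_barcode") |>
    tidyr::pivot_longer(-"cell_barcode", names_to = "label",
      values_to = "score") |>
    mutate(
      call = unname(x$call[.data$cell_barcode]),
      flagged = unname(x$flagged[.data$cell_barcode])
    )
}

#' @export
glance.correlation_model <- function(x, ...) {
  tibble(
    n_reference_cells = length(x$labels),
    n_labels = length(unique(x$labels)),
    n_marker_genes = length(x$marker_genes),
    score_quantile = x$score_quantile,
    granularity = attr(x, "granularity")
  )
}
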