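# Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed and an integer or string key
#'
#' All stage- and cell-level random streams in the package derive their seeds
#' through this one documented linear-congruential hash, so that adding a stage
#' (or reordering cells) never perturbs the randomness of another stage.
#' The result is always a non-negative integer below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param key Integer or character key identifying the substream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(key)) {
    codes <- utf8ToInt(paste(key, collapse = ""))
    key <- sum(codes * (seq_along(codes) %% 97 + 1))
  }
  stopifnot(is.numeric(key), length(key) == 1L)
  # doubles stay exact: |values| < 2^53 throughout
  as.integer((abs(seed) * 69069 + abs(key) * 40503 + 1013904223) %% 2147483647)
}

# Validate a genes x cells sparse count matrix; returns it as dgCMatrix.
as_count_matrix <- function(m, arg = "m") {
  if (is.matrix(m)) m <- methods::as(m, "CsparseMatrix")
  if (!methods::is(m, "sparseMatrix")) {
    abort(sprintf("`%s` must be a (sparse) matrix of counts", arg))
  }
  # normalize pattern/symmetric/triplet variants to numeric general CsparseMatrix
  m <- methods::as(methods::as(methods::as(m, "generalMatrix"), "dMatrix"),
    "CsparseMatrix")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    bad <- which(x < 0 | x != round(x))[1]
    coord <- nonzero_coord(m, bad)
    abort(sprintf(
      "count matrix has a negative or non-integer entry %g at gene %d, cell %d",
      x[bad], coord[1], coord[2]
    ))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry gene rownames and cell barcode colnames", arg))
  }
  if (anyDuplicated(rownames(m))) abort("duplicated gene identifiers in count matrix")
  if (anyDuplicated(colnames(m))) abort("duplicated cell barcodes in count matrix")
  m
}

# (row, col) of the k-th stored value of a dgCMatrix
nonzero_coord <- function(m, k) {
  col <- which(m@p >= k)[1] - 1L
  c(m@i[k] + 1L, col)
}

# Column sums / expressed-gene counts that work for both dense and sparse input.
cell_totals <- function(m) Matrix::colSums(m)
cells_n_genes <- function(m) Matrix::colSums(m > 0)

# argmax over columns with lexicographic tie-break on column names
argmax_label <- function(scores) {
  labs <- colnames(scores)
  ord <- order(labs)
  s <- scores[, ord, drop = FALSE]
  idx <- apply(s, 1L, which.max)  # which.max takes the first == smallest label
  labs[ord][idx]
}

`%||%` <- rlang::`%||%`
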