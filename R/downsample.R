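# Depth and gene downsampling.
#
# The depth transform is a per-gene multiplicative Poisson factor, not
# classical binomial thinning: each gene of a cell draws an independent
# Poisson(lambda) deviate with lambda = target / total, and the gene's whole
# count is multiplied by that deviate. A gene therefore either drops to zero,
# survives unchanged (x1) or is amplified (x2, x3, ...); the expected cell
# total after the transform is lambda x total = target.

#' Poisson probability mass function
#'
#' The mass function \eqn{p(x) = \lambda^x e^{-\lambda} / x!} of the per-gene
#' multiplicative factor used by [downsample_cell()].
#'
#' @param x Non-negative integer (vectorized).
#' @param lambda Non-negative rate; `target / total` in the depth transform.
#' @return `P(X = x)` for `X ~ Poisson(lambda)`.
#' @export
poisson_pmf <- function(x, lambda) {
  if (any(x < 0) || any(x != round(x))) abort("`x` must be non-negative integer")
  if (any(lambda < 0)) abort("`lambda` must be non-negative")
  exp(x * log(ifelse(lambda == 0 & x == 0, 1, lambda)) - lambda - lgamma(x + 1))
}

#' Downsample one cell to a target UMI depth
#'
#' Multiplies each gene's count by an independent Poisson(lambda) deviate with
#' `lambda = target / total`. In `"paper_literal"` mode the rate may exceed 1
#' for cells shallower than the target (the cell is up-sampled in
#' expectation); `"capped"` mode clips the rate at 1 so shallow cells are, in
#' expectation, left alone. `"binomial_thinning"` is a comparison mode that
#' instead draws `Binomial(count, min(1, lambda))` per gene — the classical
#' thinning transform, not the multiplicative-factor one.
#'
#' Cells with zero total pass through unchanged (the rate is undefined).
#'
#' @param counts Non-negative integer vector of per-gene counts.
#' @param target Target UMI depth (non-negative integer).
#' @param mode One of `"paper_literal"` (default), `"capped"`,
#'   `"binomial_thinning"`.
#' @param seed Optional integer; when given, seeds the draw locally.
#' @return An integer vector of the same length (and names) as `counts`.
#' @export
downsample_cell <- function(counts, target,
                            mode = c("paper_literal", "capped",
                              "binomial_thinning"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  if (target < 0) abort("`target` must be non-negative")
  total <- sum(counts)
  if (total == 0) return(counts)
  if (!is.null(seed)) set.seed(seed)
  lam <- target / total
  if (mode != "paper_literal") lam <- min(1, lam)
  if (mode == "binomial_thinning") {
    out <- rbinom(length(counts), size = as.integer(counts), prob = lam)
  } else {
    factors <- rpois(length(counts), lam)
    out <- as.integer(counts) * factors
  }
  setNames(as.integer(out), names(counts))
}

#' Downsample every cell of a matrix to a target depth
#'
#' Applies [downsample_cell()] independently to each cell. Each cell draws
#' from its own substream seeded by `derive_seed(seed, cell barcode)`, so the
#' result is deterministic given `seed` and invariant to cell order.
#'
#' @param m Genes x cells count matrix.
#' @inheritParams downsample_cell
#' @param seed Integer seed for the whole matrix.
#' @return A count matrix with the same dimnames.
#' @export
downsample_matrix <- function(m, target,
                              mode = c("paper_literal", "capped",
                                "binomial_thinning"),
                              seed = 1L) {
  mode <- match.arg(mode)
  m <- as_count_matrix(m)
  if (target == 0 && mode != "binomial_thinning") {
    # lambda = 0 forces every factor to 0
    out <- sparseMatrix(i = integer(), j = integer(), x = double(),
      dims = dim(m), dimnames = dimnames(m))
    return(methods::as(out, "CsparseMatrix"))
  }
  n_genes <- nrow(m)
  totals <- cell_totals(m)
  p <- m@p
  xs <- vector("list", ncol(m))
  is <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    idx <- if (p[j + 1] > p[j]) (p[j] + 1):p[j + 1] else integer()
    if (totals[j] == 0) next
    set.seed(derive_seed(seed, colnames(m)[j]))
    lam <- target / totals[j]
    if (mode != "paper_literal") lam <- min(1, lam)
    if (mode == "binomial_thinning") {
      # one draw per gene, in gene order, as in the factor modes
      sizes <- integer(n_genes)
      sizes[m@i[idx] + 1L] <- as.integer(m@x[idx])
      draws <- rbinom(n_genes, size = sizes, prob = lam)
      newx <- draws[m@i[idx] + 1L]
    } else {
      factors <- rpois(n_genes, lam)
      newx <- m@x[idx] * factors[m@i[idx] + 1L]
    }
    keep <- newx > 0
    xs[[j]] <- newx[keep]
    is[[j]] <- m@i[idx][keep]
  }
  lens <- lengths(xs)
  out <- sparseMatrix(
    i = unlist(is) + 1L,
    j = rep.int(seq_len(ncol(m)), lens),
    x = as.double(unlist(xs)),
    dims = dim(m), dimnames = dimnames(m)
  )
  methods::as(out, "CsparseMatrix")
}

#' Binarize a count matrix
#'
#' @param m Genes x cells count matrix.
#' @return The same matrix with every entry replaced by `1` if the original
#'   count was `>= 1`, else `0`.
#' @export
binarize <- function(m) {
  m <- as_count_matrix(m)
  m@x[] <- as.double(m@x >= 1)
  drop0(m)
}

#' Downsample the number of expressed genes per cell
#'
#' For every cell expressing more than `max_genes` genes, a uniformly random
#' subset of the excess expressed genes is silenced (set to zero) so that
#' exactly `max_genes` genes remain expressed; cells at or below the cap are
#' untouched. `output_mode = "binary"` returns the resulting binary matrix;
#' `"restore_counts"` puts each surviving gene's original count back.
#'
#' @param m Genes x cells count matrix.
#' @param max_genes Cap on expressed genes per cell.
#' @param output_mode `"binary"` or `"restore_counts"`.
#' @param seed Integer seed; per-cell substreams as in [downsample_matrix()].
#' @return A count matrix with the same dimnames.
#' @export
downsample_genes <- function(m, max_genes,
                             output_mode = c("binary", "restore_counts"),
                             seed = 1L) {
  output_mode <- match.arg(output_mode)
  m <- as_count_matrix(m)
  if (max_genes < 0) abort("`max_genes` must be non-negative")
  m <- drop0(m)
  p <- m@p
  keep <- logical(length(m@x))
  for (j in seq_len(ncol(m))) {
    idx <- if (p[j + 1] > p[j]) (p[j] + 1):p[j + 1] else integer()
    e <- length(idx)
    if (e <= max_genes) {
      keep[idx] <- TRUE
    } else {
      set.seed(derive_seed(seed, colnames(m)[j]))
      keep[sample(idx, max_genes)] <- TRUE
    }
  }
  out <- m
  out@x[!keep] <- 0
  out <- drop0(out)
  if (output_mode == "binary") binarize(out) else out
}
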