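# One-vs-rest marker-gene discovery. Feature space for the gene-pair random
# forest; deliberately mirrors the conventions of the standard single-cell
# toolkits: expression fraction (pct) gates, natural-log fold change of
# depth-normalized means with pseudocount 1, Bonferroni adjustment across all
# genes per label.

#' Marker selection parameters
#'
#' @param min_pct Minimum fraction of in-group cells expressing the gene.
#' @param logfc_threshold Minimum natural-log fold change of depth-normalized
#'   (counts-per-10k, pseudocount 1) mean expression, in-group over rest.
#' @param max_cells_per_ident Cap on cells sampled per side of each
#'   one-vs-rest comparison.
#' @param test `"wilcoxon"` (rank-sum on normalized expression, default) or
#'   `"negbinom"` (negative-binomial likelihood-ratio test on raw counts with
#'   a log-depth offset).
#' @param alpha Adjusted-p significance gate.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`; applied per label
#'   across all genes in the matrix.
#' @return A list of class `marker_params`.
#' @export
marker_params <- function(min_pct = 0.5, logfc_threshold = 0.5,
                          max_cells_per_ident = 2000,
                          test = c("wilcoxon", "negbinom"), alpha = 0.05,
                          p_adjust = c("bonferroni", "BH")) {
  stopifnot(min_pct >= 0, min_pct <= 1, logfc_threshold >= 0,
    max_cells_per_ident >= 1)
  structure(
    list(min_pct = min_pct, logfc_threshold = logfc_threshold,
      max_cells_per_ident = max_cells_per_ident, test = match.arg(test),
      alpha = alpha, p_adjust = match.arg(p_adjust)),
    class = "marker_params"
  )
}

#' One-vs-rest marker genes per label
#'
#' For each label: both sides of the one-vs-rest comparison are subsampled to
#' `max_cells_per_ident` cells; `pct_in` / `pct_out` are the expressing-cell
#' fractions; the log fold change is taken on counts-per-10k means with
#' pseudocount 1 (natural log). Genes passing the `min_pct` and fold-change
#' gates are tested, p-values adjusted per label across all genes of the
#' matrix, and genes with adjusted p below `alpha` are returned ranked by
#' descending log fold change.
#'
#' @param m Genes x cells raw count matrix.
#' @param labels Label table covering the cells of `m` at one granularity.
#' @param params A [marker_params()] object.
#' @param seed Integer seed (subsampling is the only stochastic step).
#' @return A tibble of class `marker_set` with columns `label`, `gene`,
#'   `log_fc`, `pct_in`, `pct_out`, `p_value`, `p_adj`.
#' @export
find_markers <- function(m, labels, params = marker_params(), seed = 1L) {
  m <- as_count_matrix(m)
  labels <- validate_labels(labels)
  labels <- labels[labels$cell_barcode %in% colnames(m), ]
  lab_vec <- setNames(labels$label, labels$cell_barcode)
  cells <- names(lab_vec)
  groups <- split(cells, lab_vec[cells])
  if (length(groups) < 2) abort("need at least 2 labels to find markers")
  too_small <- names(groups)[lengths(groups) < 3]
  if (length(too_small)) {
    abort(sprintf("label(s) with fewer than 3 cells: %s",
      paste(too_small, collapse = ", ")))
  }
  totals <- cell_totals(m)
  # counts-per-10k normalization, kept sparse
  norm <- m %*% Matrix::Diagonal(ncol(m), ifelse(totals > 0, 1e4 / totals, 0))
  dimnames(norm) <- dimnames(m)
  n_genes <- nrow(m)

  out <- imap(groups, function(in_cells, lab) {
    rest <- setdiff(cells, in_cells)
    set.seed(derive_seed(seed, lab))
    if (length(in_cells) > params$max_cells_per_ident) {
      in_cells <- sample(in_cells, params$max_cells_per_ident)
    }
    if (length(rest) > params$max_cells_per_ident) {
      rest <- sample(rest, params$max_cells_per_ident)
    }
    m_in <- norm[, in_cells, drop = FALSE]
    m_out <- norm[, rest, drop = FALSE]
    pct_in <- rowSums(m_in > 0) / ncol(m_in)
    pct_out <- rowSums(m_out > 0) / ncol(m_out)
    log_fc <- log((rowSums(m_in) / ncol(m_in) + 1) /
        (rowSums(m_out) / ncol(m_out) + 1))
    pass <- which(pct_in >= params$min_pct & log_fc >= params$logfc_threshold)
    if (!length(pass)) {
      warn(sprintf("no gene passes the marker gates for label '%s'", lab))
      return(tibble(label = character(), gene = character(), log_fc = double(),
        pct_in = double(), pct_out = double(), p_value = double(),
        p_adj = double()))
    }
    pv <- map_dbl(pass, function(g) {
      marker_test(
        raw_in = m[g, in_cells], raw_out = m[g, rest],
        norm_in = m_in[g, ], norm_out = m_out[g, ],
        depth_in = totals[in_cells], depth_out = totals[rest],
        test = params$test
      )
    })
    p_adj <- pmin(1, switch(params$p_adjust,
      bonferroni = pv * n_genes,
      BH = p.adjust(pv, "BH")  # over tested genes; conservative vs full set
    ))
    tibble(
      label = lab, gene = rownames(m)[pass], log_fc = log_fc[pass],
      pct_in = pct_in[pass], pct_out = pct_out[pass],
      p_value = pv, p_adj = p_adj
    ) |>
      filter(.data$p_adj <= params$alpha) |>
      arrange(desc(.data$log_fc))
  })
  res <- list_rbind(out[sort(names(out))])
  attr(res, "params") <- params
  class(res) <- c("marker_set", class(res))
  res
}

marker_test <- function(raw_in, raw_out, norm_in, norm_out,
                        depth_in, depth_out, test) {
  if (test == "wilcoxon") {
    stats::wilcox.test(as.numeric(norm_in), as.numeric(norm_out),
      exact = FALSE)$p.value
  } else {
    y <- c(as.numeric(raw_in), as.numeric(raw_out))
    grp <- factor(rep(c("in", "out"), c(length(raw_in), length(raw_out))))
    off <- log(pmax(c(depth_in, depth_out), 1))
    p <- tryCatch({
      full <- suppressWarnings(MASS::glm.nb(y ~ grp + offset(off)))
      null <- suppressWarnings(MASS::glm.nb(y ~ 1 + offset(off)))
      stats::pchisq(2 * (as.numeric(stats::logLik(full)) -
          as.numeric(stats::logLik(null))), df = 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
    if (is.na(p)) 1 else p
  }
}
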