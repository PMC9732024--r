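# Reading and writing count matrices and cell label tables.
#
# On disk the matrix follows the 10x convention: genes are rows, cells are
# columns, Matrix Market indices are 1-based. In memory the matrix is a
# 0-based-free dgCMatrix indexed like any R matrix; `counts(m, cells_as_rows =
# TRUE)` exposes the transposed orientation explicitly.

#' Read a UMI count matrix
#'
#' Reads a genes x cells UMI count matrix either from a 10x-style Matrix
#' Market triplet (`matrix.mtx` with sibling `features.tsv`/`genes.tsv` and
#' `barcodes.tsv`, any of them optionally gzip-compressed) or from a dense CSV
#' with a leading `gene` column and one column per cell barcode.
#'
#' @param path For `dialect = "mtx_triplet"`, the `.mtx` file or the directory
#'   containing the triplet; for `dialect = "dense_csv"`, the CSV file.
#' @param dialect One of `"mtx_triplet"`, `"dense_csv"`.
#' @return A sparse integer [Matrix::dgCMatrix-class] (genes x cells) with
#'   gene rownames and cell-barcode colnames, in on-disk order.
#' @export
read_count_matrix <- function(path, dialect = c("mtx_triplet", "dense_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") read_mtx_triplet(path) else read_dense_csv(path)
}

find_sibling <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  abort(sprintf(
    "no %s file found in '%s'", paste(stems, collapse = " / "), dir
  ))
}

read_id_column <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  tab[[1]]
}

read_mtx_triplet <- function(path) {
  if (!file.exists(path)) abort(sprintf("path '%s' does not exist", path))
  if (dir.exists(path)) {
    dir <- path
    mtx <- find_sibling(dir, c("matrix.mtx"))
  } else {
    dir <- dirname(path)
    mtx <- path
  }
  features <- find_sibling(dir, c("features.tsv", "genes.tsv"))
  barcodes <- find_sibling(dir, c("barcodes.tsv"))
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx
  m <- Matrix::readMM(con)
  genes <- read_id_column(features)
  cells <- read_id_column(barcodes)
  if (nrow(m) != length(genes)) {
    abort(sprintf(
      "matrix has %d rows but %d features listed in '%s'",
      nrow(m), length(genes), features
    ))
  }
  if (ncol(m) != length(cells)) {
    abort(sprintf(
      "matrix has %d columns but %d barcodes listed in '%s'",
      ncol(m), length(cells), barcodes
    ))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  as_count_matrix(m)
}

read_dense_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("path '%s' does not exist", path))
  tab <- readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene" %in% names(tab)) abort("dense CSV must have a 'gene' column")
  genes <- tab$gene
  vals <- as.matrix(tab[setdiff(names(tab), "gene")])
  rownames(vals) <- genes
  as_count_matrix(vals)
}

#' Write a UMI count matrix
#'
#' Inverse of [read_count_matrix()]: writes either a Matrix Market triplet
#' (`matrix.mtx` + `features.tsv` + `barcodes.tsv` inside `path`, created if
#' needed) or a dense CSV. Round-trips are exact.
#'
#' @param m Genes x cells count matrix.
#' @param path Output directory (`mtx_triplet`) or CSV file (`dense_csv`).
#' @inheritParams read_count_matrix
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, dialect = c("mtx_triplet", "dense_csv")) {
  dialect <- match.arg(dialect)
  m <- as_count_matrix(m)
  if (dialect == "mtx_triplet") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(drop0(m), file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(x = rownames(m)), file.path(path, "features.tsv"),
      col_names = FALSE)
    readr::write_tsv(tibble(x = colnames(m)), file.path(path, "barcodes.tsv"),
      col_names = FALSE)
  } else {
    dense <- as.matrix(m)
    out <- bind_cols(tibble(gene = rownames(m)), as_tibble(dense))
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Read or write a cell label table
#'
#' A label table is a tibble with columns `cell_barcode`, `label`,
#' `granularity` (`"lineage"` or `"cell_type"`) and optionally `sample_id`;
#' one row per (barcode, granularity).
#'
#' @param path A TSV (default) or CSV file; the delimiter is chosen from the
#'   file extension.
#' @return `read_labels()` returns the validated tibble; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("path '%s' does not exist", path))
  reader <- if (grepl("\\.csv(\\.gz)?$", path)) readr::read_csv else readr::read_tsv
  tab <- reader(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  validate_labels(tab)
}

#' @rdname read_labels
#' @param labels A label table.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  writer <- if (grepl("\\.csv$", path)) readr::write_csv else readr::write_tsv
  writer(labels, path)
  invisible(path)
}

validate_labels <- function(labels) {
  labels <- as_tibble(labels)
  for (col in c("cell_barcode", "label")) {
    if (!col %in% names(labels)) {
      abort(sprintf("label table is missing required column '%s'", col))
    }
  }
  if (!"granularity" %in% names(labels)) labels$granularity <- "cell_type"
  bad <- setdiff(unique(labels$granularity), c("lineage", "cell_type"))
  if (length(bad)) {
    abort(sprintf("unknown granularity value(s): %s", paste(bad, collapse = ", ")))
  }
  dup <- labels |>
    count(.data$cell_barcode, .data$granularity) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicated (cell_barcode, granularity) rows: %s",
      paste(utils::head(dup$cell_barcode, 5), collapse = ", ")
    ))
  }
  labels
}
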