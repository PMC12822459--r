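#' Construct an expression matrix
#'
#' The package's central container: a gene x entity numeric matrix (entities
#' are cells or spatial bins) with unique ordered identifiers on both axes and
#' a layer tag recording whether the values are raw counts or log-normalized
#' expression.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, genes in rows,
#'   entities (cells/bins) in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing rownames.
#' @param entity_ids character vector of unique cell/bin identifiers; defaults
#'   to existing colnames.
#' @param layer `"counts"` (non-negative integers expected) or `"lognorm"`.
#' @return an object of class `expr_matrix` (a list with elements `values`,
#'   `gene_ids`, `entity_ids`, `layer`).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              entity_ids = colnames(values),
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(entity_ids)) {
    stop("gene_ids and entity_ids are required (or set dimnames on 'values')")
  }
  gene_ids <- as.character(gene_ids)
  entity_ids <- as.character(entity_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") != nrow(values) (",
         nrow(values), ")")
  }
  if (length(entity_ids) != ncol(values)) {
    stop("entity_ids length (", length(entity_ids), ") != ncol(values) (",
         ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(entity_ids)) stop("duplicate entity identifiers")
  if (layer == "counts" && length(values)) {
    mn <- if (inherits(values, "sparseMatrix")) min(values@x, 0) else min(values)
    if (is.finite(mn) && mn < 0) stop("negative values in a counts layer")
  }
  dimnames(values) <- list(gene_ids, entity_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 entity_ids = entity_ids, layer = layer),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d entities, layer = %s\n",
              length(x$gene_ids), length(x$entity_ids), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

stopifnot_counts <- function(mat) {
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  if (mat$layer != "counts") stop("a counts layer is required, got '",
                                  mat$layer, "'")
  invisible(mat)
}

#' Read an expression matrix from disk
#'
#' Supports the MatrixMarket triplet layout (`matrix.mtx` plus `genes.tsv` and
#' `barcodes.tsv` with one identifier per line, 1-based coordinates per the
#' MatrixMarket standard) and dense CSV with gene identifiers in the first
#' column and a header row of entity identifiers.
#'
#' @param path for `format = "mtx"` a directory containing `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`; for `format = "csv"` a CSV file.
#' @param format `"mtx"` or `"csv"`.
#' @param layer layer tag to attach, default `"counts"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("mtx", "csv"),
                            layer = c("counts", "lognorm")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- Matrix::readMM(mtx)
    genes <- utils::read.table(gf, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(bf, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes)) {
      stop("matrix has ", nrow(m), " rows but genes.tsv lists ",
           length(genes), " genes")
    }
    if (ncol(m) != length(barcodes)) {
      stop("matrix has ", ncol(m), " columns but barcodes.tsv lists ",
           length(barcodes), " barcodes")
    }
    expression_matrix(m, genes, barcodes, layer = layer)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    expression_matrix(as.matrix(df), rownames(df), colnames(df), layer = layer)
  }
}

#' Write an expression matrix to disk
#'
#' @param mat an [expression_matrix()].
#' @param path output directory (`"mtx"`) or CSV file path (`"csv"`).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::Matrix(mat$values, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(mat$gene_ids, file.path(path, "genes.tsv"))
    writeLines(mat$entity_ids, file.path(path, "barcodes.tsv"))
  } else {
    df <- as.data.frame(as.matrix(mat$values))
    utils::write.csv(df, path, row.names = TRUE)
  }
  invisible(path)
}
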