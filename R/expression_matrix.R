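#' ExpressionMatrix: sparse cells x genes counts with an optional
#' normalized layer
#'
#' The container every pipeline stage operates on. Counts are stored as a
#' sparse `dgCMatrix` oriented cells x genes; the optional `normalized`
#' layer (see [log_normalize()]) shares the sparsity pattern of the counts.
#'
#' @param counts numeric matrix or Matrix, cells as rows, genes as columns.
#'   Row names are cell IDs, column names are gene IDs; both must be unique
#'   and all entries non-negative.
#' @param normalized optional matrix of the same shape; must be zero exactly
#'   where `counts` is zero.
#' @param meta named character vector of free-form annotations
#'   (species, stage, source, ...).
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(counts, normalized = NULL, meta = character()) {
  counts <- as_cell_gene_sparse(counts)
  # Matrix drops zero-length dimnames, so 0-extent dimensions are exempt
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry cell IDs (rownames) and gene IDs (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (length(counts@x) && min(counts@x) < 0)
    stop("counts must be non-negative")
  if (!is.null(normalized)) {
    normalized <- as_cell_gene_sparse(normalized)
    dimnames(normalized) <- dimnames(counts)
    check_same_zero_pattern(counts, normalized)
  }
  structure(
    list(counts = counts, normalized = normalized,
         meta = as.character(meta) |> stats::setNames(names(meta))),
    class = "ExpressionMatrix")
}

# Coerce to dgCMatrix with explicit zeros dropped.
as_cell_gene_sparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m * 1.0, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::drop0(m)
}

check_same_zero_pattern <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("normalized layer dimensions differ from counts")
  if (!identical(a@i, b@i) || !identical(a@p, b@p))
    stop("normalized layer must be zero exactly where counts are zero")
  invisible(TRUE)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%d non-zero counts)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(" layers:", paste(c("counts", if (!is.null(x$normalized)) "normalized"),
                        collapse = ", "), "\n")
  if (length(x$meta))
    cat(" meta:", paste(names(x$meta), x$meta, sep = "=", collapse = "; "),
        "\n")
  invisible(x)
}

#' Cell and gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of IDs.
#' @export
cell_ids <- function(x) rownames(x$counts) %||% character()

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$counts) %||% character()

#' Extract an expression layer as a sparse matrix
#' @param x an `ExpressionMatrix`.
#' @param layer `"counts"` or `"normalized"`.
#' @return A `dgCMatrix`, cells x genes.
#' @export
expression_layer <- function(x, layer = c("normalized", "counts")) {
  layer <- match.arg(layer)
  if (layer == "normalized") {
    if (is.null(x$normalized))
      stop("no normalized layer present; run log_normalize() first")
    x$normalized
  } else {
    x$counts
  }
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects a directory holding a Matrix Market coordinate file
#' (`matrix.mtx[.gz]` or the only `*.mtx[.gz]`) plus one-column
#' `barcodes.tsv[.gz]` and `features.tsv[.gz]` (or `genes.tsv[.gz]`)
#' tables. The on-disk orientation is detected by matching the matrix
#' dimensions against the label-table lengths: the common 10x dialect
#' stores genes as rows and is transposed on load, so the returned object
#' is always cells x genes. Duplicate gene IDs are aggregated by
#' summation with a warning.
#'
#' @param dir path to the triplet directory.
#' @param meta named character vector stored on the result.
#' @return An [ExpressionMatrix()].
#' @export
read_mtx <- function(dir, meta = character()) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  mtx_file <- find_one(dir, c("matrix.mtx", "matrix.mtx.gz"),
                       "\\.mtx(\\.gz)?$")
  bc_file  <- find_one(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft_file  <- find_one(dir, c("features.tsv", "features.tsv.gz",
                              "genes.tsv", "genes.tsv.gz"))
  barcodes <- read_label_column(bc_file)
  features <- read_label_column(ft_file)
  m <- tryCatch(Matrix::readMM(mtx_file), error = function(e)
    stop("parse error in ", mtx_file, ": ", conditionMessage(e),
         call. = FALSE))
  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)               # 10x dialect: genes as rows
  } else if (!(nrow(m) == nb && ncol(m) == nf)) {
    stop("format error in ", mtx_file, ": matrix is ", nrow(m), " x ",
         ncol(m), " but ", bc_file, " lists ", nb, " barcodes and ",
         ft_file, " lists ", nf, " features")
  }
  m <- as_cell_gene_sparse(m)
  rownames(m) <- barcodes
  if (anyDuplicated(barcodes))
    stop("format error in ", bc_file, ": duplicate cell barcodes: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  colnames(m) <- features
  m <- aggregate_duplicate_genes(m)
  ExpressionMatrix(m, meta = meta)
}

find_one <- function(dir, names, fallback_regex = NULL) {
  for (n in names) {
    p <- file.path(dir, n)
    if (file.exists(p)) return(p)
  }
  if (!is.null(fallback_regex)) {
    hits <- list.files(dir, pattern = fallback_regex, full.names = TRUE)
    if (length(hits) == 1) return(hits)
  }
  stop("format error: none of ", paste(names, collapse = "/"),
       " found in ", dir)
}

read_label_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # tolerate multi-column feature tables (10x writes id, name, type)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

aggregate_duplicate_genes <- function(m) {
  g <- colnames(m)
  if (!anyDuplicated(g)) return(m)
  dup <- unique(g[duplicated(g)])
  warning("duplicate gene IDs aggregated by summation: ",
          paste(dup, collapse = ", "))
  lev <- unique(g)
  fac <- factor(g, levels = lev)
  agg <- Matrix::sparseMatrix(i = seq_along(fac), j = as.integer(fac),
                              x = 1, dims = c(length(fac), length(lev)))
  out <- m %*% agg
  colnames(out) <- lev
  rownames(out) <- rownames(m)
  as_cell_gene_sparse(out)
}

#' Write an ExpressionMatrix as a Matrix Market triplet directory
#'
#' Writes the counts layer in the 10x dialect (genes as rows) together
#' with `barcodes.tsv` and `features.tsv`, so that [read_mtx()] round-trips
#' integer counts bit-exactly.
#'
#' @param x an `ExpressionMatrix`.
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(x), file.path(dir, "barcodes.tsv"))
  writeLines(gene_ids(x), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a dense labelled expression table
#'
#' @param path CSV (`.csv`) or TSV file with one label row and one label
#'   column.
#' @param orientation `"cells-as-rows"` or `"genes-as-rows"`; the latter is
#'   transposed so the result is always cells x genes.
#' @param meta named character vector stored on the result.
#' @return An [ExpressionMatrix()].
#' @export
read_dense_table <- function(path,
                             orientation = c("cells-as-rows",
                                             "genes-as-rows"),
                             meta = character()) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, comment.char = ""),
    error = function(e)
      stop("parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE))
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop("parse error in ", path, ": non-numeric entries")
  if (any(m < 0))
    stop("value-domain error in ", path, ": negative entries not allowed")
  if (orientation == "genes-as-rows") m <- t(m)
  ExpressionMatrix(m, meta = meta)
}
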