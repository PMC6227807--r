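#' Expression matrix container
#'
#' An `expression_matrix` holds a cells-by-genes table of non-negative
#' continuous expression values together with a population label per cell.
#' A value of exactly 0 means "no measurable expression" (undetected); the
#' binarization rule ([binarize()]) is built on that convention.
#'
#' @param values Numeric matrix, rows = cells, columns = genes. All values
#'   must be finite and >= 0.
#' @param cell_ids Character vector of unique cell identifiers
#'   (default: rownames of `values`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: colnames of `values`).
#' @param population Character vector, one population label per cell.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (matrix with `cell_ids` as rownames and `gene_ids` as
#'   colnames) and `population` (character vector along rows).
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(0, 3.2, 1e-4, 0), 2, 2),
#'                        cell_ids = c("c1", "c2"),
#'                        gene_ids = c("gA", "gB"),
#'                        population = c("P", "P"))
#' binarize(m)
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values), population) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (cells x genes)", call. = FALSE)
  if (is.null(cell_ids))
    cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids))
    gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || anyDuplicated(cell_ids))
    stop("cell ids must be unique and match the number of rows", call. = FALSE)
  if (length(gene_ids) != ncol(values) || anyDuplicated(gene_ids))
    stop("gene ids must be unique and match the number of columns", call. = FALSE)
  if (length(population) != nrow(values) || anyNA(population))
    stop("`population` must supply one non-missing label per cell", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at cell '%s', gene '%s'",
                 cell_ids[bad[1]], gene_ids[bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, population = as.character(population)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, %d population(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$population))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Binary on/off call matrix
#'
#' Same shape and labels as the source [expression_matrix()], but entries are
#' 0/1 detection calls.
#'
#' @param calls Integer 0/1 matrix, rows = cells, columns = genes.
#' @param population Character vector of per-cell population labels.
#' @return An object of class `binary_matrix`.
#' @export
binary_matrix <- function(calls, population) {
  if (!is.matrix(calls) || !all(calls %in% c(0L, 1L)))
    stop("`calls` must be a 0/1 matrix", call. = FALSE)
  if (length(population) != nrow(calls))
    stop("one population label per cell required", call. = FALSE)
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, population = as.character(population)),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d cells x %d genes, %d population(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$population))))
  invisible(x)
}

#' @export
dim.binary_matrix <- function(x) dim(x$calls)

#' Read a delimited single-cell expression table
#'
#' Expects one row per cell, a header row of gene names, a cell-id column
#' (first column by default) and a population label column. All remaining
#' columns must be numeric, non-negative expression values.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param label_column Name of the population-label column.
#' @param id_column Name of the cell-id column; `NULL` uses the first
#'   non-label column.
#' @param transpose If `TRUE` the file is genes-by-cells and is transposed
#'   after reading (the label column then refers to the transposed rows and
#'   must be supplied via `population`).
#' @param transform Expression transform applied to the numeric values:
#'   `"none"` (values already in expression space), `"guo"`
#'   ([transform_ct_guo()], input = raw Ct) or `"pina"`
#'   ([transform_dct_pina()], input = delta-Ct).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, dialect = c("csv", "tsv"),
                                  label_column = "population",
                                  id_column = NULL,
                                  transpose = FALSE,
                                  transform = c("none", "guo", "pina")) {
  dialect <- match.arg(dialect)
  transform <- match.arg(transform)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 3)
    stop(sprintf(
      "parsed only %d column(s) from %s; wrong dialect ('%s')?",
      ncol(df), path, dialect), call. = FALSE)
  if (!label_column %in% names(df))
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  pop <- as.character(df[[label_column]])
  df[[label_column]] <- NULL
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!id_column %in% names(df))
    stop(sprintf("id column '%s' not found in %s", id_column, path),
         call. = FALSE)
  ids <- as.character(df[[id_column]])
  df[[id_column]] <- NULL
  if (anyDuplicated(ids))
    stop(sprintf("duplicate cell id '%s' in %s", ids[duplicated(ids)][1], path),
         call. = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("non-numeric expression value in column '%s', row %s",
                   names(df)[j],
                   if (is.na(bad)) "?" else as.character(bad)), call. = FALSE)
    }
    if (anyNA(col))
      stop(sprintf("missing expression value in column '%s', row %d",
                   names(df)[j], which(is.na(col))[1]), call. = FALSE)
  }
  values <- as.matrix(df)
  if (transpose) values <- t(values)
  values <- switch(transform,
                   none = values,
                   guo = transform_ct_guo(values),
                   pina = transform_dct_pina(values))
  if (transform == "none" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at row %d, column '%s'",
                 bad[1], colnames(values)[bad[2]]), call. = FALSE)
  }
  expression_matrix(values, cell_ids = ids, gene_ids = colnames(values),
                    population = pop)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression_table()] (with `transform = "none"`): writes
#' cell id, population label and one numeric column per gene, at full
#' double precision.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param label_column Name used for the population column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, dialect = c("csv", "tsv"),
                                   label_column = "population") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(cell_id = rownames(m$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[label_column]] <- m$population
  vals <- as.data.frame(m$values, check.names = FALSE)
  df <- cbind(df, vals)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ct-to-expression transform (background-Ct convention)
#'
#' Converts raw qPCR Ct cycles to log2 expression above a system background:
#' `max(0, background - raw_ct)`. Ct values at or beyond the background are
#' treated as undetected and map to 0.
#'
#' @param raw_ct Numeric vector/matrix of raw Ct cycles (finite).
#' @param background Background Ct (default 28 cycles).
#' @return Non-negative expression values, same shape as `raw_ct`.
#' @export
#' @examples
#' transform_ct_guo(c(25, 28, 31))  # 3 0 0
transform_ct_guo <- function(raw_ct, background = 28) {
  if (anyNA(raw_ct) || any(!is.finite(raw_ct)))
    stop("raw Ct values must be finite", call. = FALSE)
  pmax(background - raw_ct, 0)
}

#' Delta-Ct-to-expression transform (detection-limit convention)
#'
#' Converts delta-Ct (cycles relative to a reference gene) to natural-log
#' scale expression: `(limit - delta_ct) * log(2)` for values below the
#' detection limit, and 0 at or beyond it (undetected). Binarization only
#' distinguishes detected from undetected, so downstream entropies do not
#' depend on the scale factor.
#'
#' @param delta_ct Numeric vector/matrix of delta-Ct cycles (finite).
#' @param limit Experimental detection limit (default 30 cycles).
#' @return Non-negative expression values, same shape as `delta_ct`.
#' @export
#' @examples
#' transform_dct_pina(c(29, 30, 33))  # log(2) 0 0
transform_dct_pina <- function(delta_ct, limit = 30) {
  if (anyNA(delta_ct) || any(!is.finite(delta_ct)))
    stop("delta-Ct values must be finite", call. = FALSE)
  pmax(limit - delta_ct, 0) * log(2)
}

#' Binarize expression into on/off calls
#'
#' A gene is called "on" in a cell iff its expression is strictly greater
#' than 0; exactly two levels are distinguished (undetected vs detected).
#'
#' @param m An [expression_matrix()].
#' @return A [binary_matrix()] with the same dimensions and labels.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  calls <- (m$values > 0) * 1L
  dimnames(calls) <- dimnames(m$values)
  binary_matrix(calls, m$population)
}
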