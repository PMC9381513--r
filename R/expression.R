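#' Expression matrices
#'
#' An `expr_matrix` is a genes-by-observations numeric matrix (observations
#' are cells or bulk samples) together with per-observation annotations and a
#' declared value scale, e.g. `"log2(TPM/10+1)"` for the processed
#' single-cell matrices used throughout, or `"counts"`.
#'
#' @param values numeric matrix, genes in rows (unique rownames), observations
#'   in columns (colnames).
#' @param annotations data.frame with one row per observation; must contain
#'   an `obs_id` column matching `colnames(values)`. Extra columns carry
#'   lineage / group labels.
#' @param value_scale character scale tag: `"counts"`, `"log2(TPM/10+1)"`, or
#'   any other descriptive string.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, annotations = NULL,
                              value_scale = "other") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression_matrix: genes must be named")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0L) {
    stop("expression_matrix: duplicate gene symbols: ",
         paste(dup, collapse = ", "))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("obs", seq_len(ncol(values)))
  }
  if (is.null(annotations)) {
    annotations <- data.frame(obs_id = colnames(values),
                              stringsAsFactors = FALSE)
  }
  if (!"obs_id" %in% names(annotations)) {
    stop("expression_matrix: annotations need an obs_id column")
  }
  if (!setequal(annotations$obs_id, colnames(values)) ||
      nrow(annotations) != ncol(values)) {
    stop("expression_matrix: annotations must cover every observation exactly once")
  }
  annotations <- annotations[match(colnames(values), annotations$obs_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  if (value_scale %in% c("counts", "log2(TPM/10+1)") &&
      any(values < 0, na.rm = TRUE)) {
    stop("expression_matrix: negative values on scale ", value_scale)
  }
  structure(list(values = values, annotations = annotations,
                 value_scale = value_scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d observations [%s]\n",
              nrow(x$values), ncol(x$values), x$value_scale))
  invisible(x)
}

#' Read an expression matrix from dense CSV or MatrixMarket triplet
#'
#' Dense CSV: first column holds names for the rows, header holds names for
#' the columns. MatrixMarket (`.mtx`): plain-text triplet with two sidecar
#' files listing row and column names, one per line; by default these are the
#' `.mtx` path with `_rows.txt` / `_cols.txt` substituted for `.mtx`.
#'
#' @param path file path (`.csv` or `.mtx`).
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`,
#'   describing the file layout; the returned matrix is always
#'   genes x observations.
#' @param value_scale scale tag stored on the result.
#' @param annotations optional per-observation annotation data.frame.
#' @param row_names,col_names sidecar paths for `.mtx` input.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "genes_in_columns"),
                                   value_scale = "other",
                                   annotations = NULL,
                                   row_names = NULL, col_names = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("read_expression_matrix: file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(row_names)) row_names <- sub("\\.mtx$", "_rows.txt", path)
    if (is.null(col_names)) col_names <- sub("\\.mtx$", "_cols.txt", path)
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
  } else {
    d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d[[1L]]
  }
  if (orientation == "genes_in_columns") m <- t(m)
  expression_matrix(m, annotations = annotations, value_scale = value_scale)
}

#' Write an expression matrix as dense CSV
#' @param x an `expr_matrix`.
#' @param path output CSV path (genes in rows).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_precise(df, path)
  invisible(path)
}

#' Gene signature sets
#'
#' A `signature_set` is a named list of gene-symbol vectors, e.g. the immune
#' cell population signatures and inflammation signatures used for bulk
#' scoring.
#'
#' @param x named list of character vectors.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(x) {
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x))) {
    stop("signature_set: signatures must have unique nonempty names")
  }
  if (any(lengths(x) == 0L)) stop("signature_set: empty gene list")
  structure(lapply(x, as.character), class = "signature_set")
}

#' Read gene signatures from two-column CSV or GMT
#'
#' CSV format: header `signature,gene`, one gene per row. GMT: one signature
#' per line, tab-separated `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path; format chosen by extension (`.gmt` vs anything else).
#' @return a `signature_set`.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("read_signatures: file not found: ", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sigs <- lapply(parts, function(p) p[-(1:2)])
    names(sigs) <- vapply(parts, `[`, "", 1L)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("signature", "gene") %in% names(d))) {
      stop("read_signatures: CSV needs columns signature,gene")
    }
    sigs <- split(d$gene, d$signature)
  }
  signature_set(sigs)
}
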