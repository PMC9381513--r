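#' Cell feature tables
#'
#' A `cell_table` holds one segmented-cell feature table: per-cell centroid
#' coordinates in micrometers, per-cycle nuclear (DNA) stain intensities, and
#' per-marker mean fluorescence intensities, together with sample / core /
#' patient identifiers. It is the common currency of the QC, typing, spatial
#' correlation, and neighborhood modules.
#'
#' @param data data.frame with columns `cell_id`, `sample_id`, `core_id`,
#'   `patient_id`, `x_um`, `y_um` plus the DNA and marker columns named below.
#' @param marker_cols character vector of marker column names in `data`.
#' @param dna_cols character vector of per-cycle DNA column names in `data`,
#'   in cycle order.
#' @return An object of class `cell_table`: a list with elements `data`
#'   (the data.frame), `marker_cols`, and `dna_cols`.
#' @export
cell_table <- function(data, marker_cols, dna_cols) {
  stopifnot(is.data.frame(data))
  required <- c("cell_id", "sample_id", "core_id", "patient_id", "x_um", "y_um")
  missing_cols <- setdiff(c(required, marker_cols, dna_cols), names(data))
  if (length(missing_cols) > 0L) {
    stop("cell_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  obj <- structure(
    list(
      data = as.data.frame(data, check.names = FALSE),
      marker_cols = as.character(marker_cols),
      dna_cols = as.character(dna_cols)
    ),
    class = "cell_table"
  )
  validate_cell_table(obj)
  obj
}

validate_cell_table <- function(x) {
  d <- x$data
  if (!all(is.finite(d$x_um)) || !all(is.finite(d$y_um))) {
    stop("cell_table: non-finite coordinates")
  }
  for (sid in unique(d$sample_id)) {
    ids <- d$cell_id[d$sample_id == sid]
    if (anyDuplicated(ids)) {
      stop("cell_table: duplicate cell_id within sample ", sid)
    }
  }
  for (col in c(x$marker_cols, x$dna_cols)) {
    v <- d[[col]]
    if (!is.numeric(v)) stop("cell_table: column ", col, " is not numeric")
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0L) {
      stop("cell_table: negative intensity in column ", col,
           " at row ", bad[1L])
    }
  }
  invisible(x)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "cell_table: %d cells, %d markers, %d DNA cycles, %d sample(s)\n",
    nrow(x$data), length(x$marker_cols), length(x$dna_cols),
    length(unique(x$data$sample_id))
  ))
  cat("markers:", paste(x$marker_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a cell table
#' @param x a `cell_table`.
#' @return integer count of rows.
#' @export
n_cells <- function(x) nrow(x$data)

#' Default column schema for reading cell feature tables
#'
#' Maps the column layout of an MCMICRO-style quantification CSV onto the
#' internal field names. `dna_pattern` is a regular expression selecting the
#' per-cycle DNA columns (matched in file order). Columns not named by the
#' schema are treated as markers when `extra = "markers"`, or dropped when
#' `extra = "drop"`. `aliases` maps vendor variants of marker names onto
#' canonical names at read time. `scale_um_per_unit` converts stored
#' coordinate units (e.g. pixels) to micrometers.
#'
#' @param cell_id,x,y,sample_id,core_id,patient_id column names in the file;
#'   the last three may be absent, in which case constant defaults are used.
#' @param dna_pattern regex for DNA columns.
#' @param markers explicit marker column names, or `NULL` to auto-detect.
#' @param extra what to do with unlisted columns: `"markers"` or `"drop"`.
#' @param aliases named character vector, `c(file_name = canonical_name)`.
#' @param scale_um_per_unit numeric scale factor applied to coordinates.
#' @return a schema list understood by [read_cell_table()].
#' @export
cell_schema <- function(cell_id = "CellID", x = "X_centroid", y = "Y_centroid",
                        sample_id = "Sample", core_id = "Core",
                        patient_id = "Patient",
                        dna_pattern = "^DNA[0-9]+$", markers = NULL,
                        extra = c("markers", "drop"), aliases = NULL,
                        scale_um_per_unit = 1) {
  list(
    cell_id = cell_id, x = x, y = y, sample_id = sample_id,
    core_id = core_id, patient_id = patient_id, dna_pattern = dna_pattern,
    markers = markers, extra = match.arg(extra), aliases = aliases,
    scale_um_per_unit = scale_um_per_unit
  )
}

#' Read a cell feature table from CSV
#'
#' Reads an MCMICRO-style single-cell quantification CSV (one row per
#' segmented cell) into a validated [cell_table()]. The schema names the
#' identifier, coordinate, and DNA columns; remaining columns become markers
#' or are dropped.
#'
#' @param path CSV file path.
#' @param schema a schema from [cell_schema()].
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path, schema = cell_schema()) {
  if (!file.exists(path)) stop("read_cell_table: file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(schema$aliases)) {
    hit <- names(raw) %in% names(schema$aliases)
    names(raw)[hit] <- unname(schema$aliases[names(raw)[hit]])
  }
  for (col in c(schema$cell_id, schema$x, schema$y)) {
    if (!col %in% names(raw)) {
      stop("read_cell_table: missing mandatory column: ", col)
    }
  }
  dna_cols <- grep(schema$dna_pattern, names(raw), value = TRUE)
  if (length(dna_cols) == 0L) {
    stop("read_cell_table: no DNA columns match pattern ", schema$dna_pattern)
  }
  opt <- function(col, default) {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  d <- data.frame(
    cell_id = raw[[schema$cell_id]],
    sample_id = opt(schema$sample_id, "sample1"),
    core_id = opt(schema$core_id, "core1"),
    patient_id = opt(schema$patient_id, "patient1"),
    x_um = raw[[schema$x]] * schema$scale_um_per_unit,
    y_um = raw[[schema$y]] * schema$scale_um_per_unit,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  known <- c(schema$cell_id, schema$x, schema$y, schema$sample_id,
             schema$core_id, schema$patient_id, dna_cols)
  if (is.null(schema$markers)) {
    marker_cols <- if (schema$extra == "markers") {
      setdiff(names(raw), known)
    } else {
      character(0)
    }
  } else {
    miss <- setdiff(schema$markers, names(raw))
    if (length(miss) > 0L) {
      stop("read_cell_table: missing marker column(s): ",
           paste(miss, collapse = ", "))
    }
    marker_cols <- schema$markers
  }
  for (col in c(dna_cols, marker_cols)) d[[col]] <- raw[[col]]
  cell_table(d, marker_cols = marker_cols, dna_cols = dna_cols)
}

#' Write a cell feature table to CSV
#'
#' Writes in the same MCMICRO-style layout that [read_cell_table()] expects,
#' with numeric values formatted at full double precision so that a
#' write/read round trip reproduces every value bit-exactly.
#'
#' @param x a `cell_table`.
#' @param path output CSV path.
#' @param schema column naming, from [cell_schema()].
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path, schema = cell_schema()) {
  d <- x$data
  out <- data.frame(row.names = seq_len(nrow(d)), check.names = FALSE)
  out[[schema$cell_id]] <- d$cell_id
  out[[schema$sample_id]] <- d$sample_id
  out[[schema$core_id]] <- d$core_id
  out[[schema$patient_id]] <- d$patient_id
  out[[schema$x]] <- d$x_um / schema$scale_um_per_unit
  out[[schema$y]] <- d$y_um / schema$scale_um_per_unit
  for (col in c(x$dna_cols, x$marker_cols)) out[[col]] <- d[[col]]
  write_csv_precise(out, path)
  invisible(path)
}

# Full-precision CSV writer: doubles serialized with %.17g survive a
# read.csv round trip bit-exactly; everything else written as-is.
write_csv_precise <- function(df, path) {
  fmt <- lapply(df, function(v) {
    if (is.double(v)) {
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- ""
      s
    } else if (is.numeric(v)) {
      as.character(v)
    } else {
      v
    }
  })
  out <- as.data.frame(fmt, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
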