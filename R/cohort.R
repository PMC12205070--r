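#' Single-cell expression cohort
#'
#' A `cohort` bundles a sparse cell-by-gene count matrix with its per-cell
#' metadata, an optional depth-normalized matrix and an optional cell-by-regulon
#' activity matrix. Rows of every matrix align one-to-one with rows of the
#' metadata tibble, keyed by `barcode`.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, cells in rows,
#'   genes in columns. Must carry unique row and column names.
#' @param cells A data frame of per-cell metadata with a `barcode` column
#'   matching `rownames(counts)`. Typical columns: `patient`, `sample`,
#'   `timepoint` (one of `"initial"`, `"relapse"`), `cluster`, `phase`,
#'   `predicted_type`.
#' @param normalized Optional matrix of log1p depth-normalized expression with
#'   the same dimnames as `counts`.
#' @param regulons Optional numeric matrix of per-cell regulon activities in
#'   `[0, 1]`, rows aligned with `counts`.
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(counts, cells, normalized = NULL, regulons = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have cell (row) and gene (column) names.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(paste0("Duplicate cell barcodes: ",
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(paste0("Duplicate gene identifiers: ",
                 paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                       collapse = ", ")))
  }
  if (any(counts@x < 0)) abort("Counts must be non-negative.")
  cells <- as_tibble(cells)
  if (!"barcode" %in% names(cells)) abort("`cells` must have a `barcode` column.")
  check_barcode_alignment(rownames(counts), cells$barcode)
  cells <- cells[match(rownames(counts), cells$barcode), , drop = FALSE]
  if ("timepoint" %in% names(cells)) {
    bad <- setdiff(unique(as.character(cells$timepoint)), c("initial", "relapse", NA))
    if (length(bad) > 0) {
      abort(paste0("Unknown timepoint value(s): ", paste(bad, collapse = ", "),
                   " (expected 'initial' or 'relapse')."))
    }
  }
  if (!is.null(normalized)) stopifnot(identical(dim(normalized), dim(counts)))
  if (!is.null(regulons)) {
    stopifnot(nrow(regulons) == nrow(counts))
    if (min(regulons) < 0 || max(regulons) > 1) {
      abort("Regulon activities must lie in [0, 1].")
    }
  }
  structure(
    list(counts = counts, cells = cells, normalized = normalized,
         regulons = regulons),
    class = "cohort"
  )
}

check_barcode_alignment <- function(matrix_bc, meta_bc) {
  missing_meta <- setdiff(matrix_bc, meta_bc)
  extra_meta <- setdiff(meta_bc, matrix_bc)
  if (length(missing_meta) > 0 || length(extra_meta) > 0) {
    msg <- "Barcodes in matrix and metadata disagree."
    if (length(missing_meta) > 0) {
      msg <- c(msg, paste0("Missing from metadata: ",
                           paste(head(missing_meta, 10), collapse = ", ")))
    }
    if (length(extra_meta) > 0) {
      msg <- c(msg, paste0("Absent from matrix: ",
                           paste(head(extra_meta, 10), collapse = ", ")))
    }
    abort(paste(msg, collapse = " "))
  }
  invisible(TRUE)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$counts), " cells x ", ncol(x$counts), " genes\n", sep = "")
  cat("  normalized: ", !is.null(x$normalized),
      " | regulons: ", if (is.null(x$regulons)) 0 else ncol(x$regulons), "\n", sep = "")
  cat("  metadata columns: ", paste(names(x$cells), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$counts)

#' Per-cell metadata of a cohort
#'
#' @param x A [cohort()].
#' @param ... Unused.
#' @return The per-cell metadata as a tibble (one row per cell).
#' @method tidy cohort
#' @export
tidy.cohort <- function(x, ...) x$cells

#' @rdname tidy.cohort
#' @export
cell_data <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$cells
}

#' Replace or extend per-cell metadata
#'
#' Joins new per-cell columns onto the cohort metadata by `barcode`.
#'
#' @param x A [cohort()].
#' @param value A data frame with a `barcode` column.
#' @return The cohort with updated metadata.
#' @export
set_cell_data <- function(x, value) {
  stopifnot(inherits(x, "cohort"))
  value <- as_tibble(value)
  check_barcode_alignment(rownames(x$counts), value$barcode)
  x$cells <- value[match(rownames(x$counts), value$barcode), , drop = FALSE]
  x
}

# normalized matrix, computing it on the fly (with a message) when absent
normalized_matrix <- function(x, target_sum = 1e4) {
  if (inherits(x, "cohort")) {
    if (is.null(x$normalized)) {
      inform("Cohort not normalized yet; applying normalize_cells() defaults.")
      x <- normalize_cells(x, target_sum = target_sum)
    }
    return(x$normalized)
  }
  x
}
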