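#' Read a cell-by-gene matrix with metadata
#'
#' Reads a Matrix Market count matrix (cells in rows) together with its gene
#' and barcode sidecar files and a per-cell metadata TSV, validates that all
#' four agree, and returns a [cohort()]. Mismatched barcodes between the
#' matrix and the metadata raise an error naming the offenders.
#'
#' @param mtx_path Matrix Market file (cells x genes).
#' @param features_path One gene identifier per line (TSV, first column used).
#' @param barcodes_path One cell barcode per line.
#' @param metadata_path TSV with a `barcode` column plus any per-cell columns.
#' @return A [cohort()].
#' @export
read_matrix <- function(mtx_path, features_path, barcodes_path, metadata_path) {
  for (p in c(mtx_path, features_path, barcodes_path, metadata_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  m <- methods::as(readMM(mtx_path), "CsparseMatrix")
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  if (nrow(m) != length(barcodes)) {
    abort(paste0("Matrix has ", nrow(m), " rows but ", length(barcodes),
                 " barcodes."))
  }
  if (ncol(m) != length(features)) {
    abort(paste0("Matrix has ", ncol(m), " columns but ", length(features),
                 " features."))
  }
  dimnames(m) <- list(barcodes, features)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  cohort(m, meta)
}

#' Write a cohort to Matrix Market plus TSV sidecars
#'
#' Inverse of [read_matrix()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv` into `dir`.
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cell_metadata.tsv"))
  writeMM(x$counts, paths[1])
  writeLines(colnames(x$counts), paths[2])
  writeLines(rownames(x$counts), paths[3])
  readr::write_tsv(x$cells, paths[4])
  invisible(paths)
}

#' Read and write gene sets in GMT format
#'
#' @param path GMT file: one tab-separated line per set
#'   (`name`, `description`, genes...).
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' @param sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a splicing-node count table
#'
#' @param path TSV with columns `cell_id`, `node_id`, `gene`, `event_type`,
#'   `incl_count`, `excl_count` (extra columns such as `patient` pass through).
#' @return A tibble.
#' @export
read_splice_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("cell_id", "node_id", "gene", "event_type", "incl_count", "excl_count")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Splice table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(tbl$incl_count < 0) || any(tbl$excl_count < 0)) {
    abort("Read counts must be non-negative.")
  }
  tbl
}
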