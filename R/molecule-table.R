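#' Per-sample molecule table
#'
#' The unit of droplet-experiment cleaning: one record per observed molecule,
#' keyed by (cell barcode, UMI, gene) within a sample, with the number of
#' reads supporting it. Records sharing a key are aggregated by summing reads,
#' so keys are unique within a table and every record has at least one read.
#'
#' @param records A data frame with columns `cell_barcode`, `umi`, `gene`
#'   (character) and `reads` (positive integers).
#' @param sample_id Sample label, stored as an attribute.
#' @return A `molecule_table`: a tibble with the four columns above,
#'   aggregated by key, carrying a `sample_id` attribute.
#' @examples
#' molecule_table(
#'   data.frame(cell_barcode = "AAAC", umi = c("U1", "U1"),
#'              gene = "GeneX", reads = c(2, 3)),
#'   sample_id = "s1"
#' )
#' @export
molecule_table <- function(records, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id))
  records <- tibble::as_tibble(records)
  need <- c("cell_barcode", "umi", "gene", "reads")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("molecule records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[need]
  if (nrow(records) > 0) {
    if (any(is.na(records$reads)) || any(records$reads < 1) ||
        any(records$reads != round(records$reads))) {
      stop("`reads` must be positive integers", call. = FALSE)
    }
    records <- dplyr::summarise(
      records,
      reads = sum(.data$reads),
      .by = c("cell_barcode", "umi", "gene")
    )
  }
  new_molecule_table(records, sample_id)
}

# fast-path constructor: `records` already satisfies the invariants
new_molecule_table <- function(records, sample_id) {
  out <- tibble::as_tibble(records)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("molecule_table", class(tibble::tibble()))
  out
}

#' @rdname molecule_table
#' @param x A `molecule_table`.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read a molecule table from disk
#'
#' Accepts tab-delimited text with header columns `cell_barcode`, `umi`,
#' `gene`, `reads`, or an HDF5 file (extension `.h5` / `.hdf5`) with four
#' parallel root-level datasets of the same names. Records with identical
#' (cell barcode, UMI, gene) are aggregated by summing reads.
#'
#' @param path File path.
#' @param sample_id Sample label for the resulting table.
#' @return A [molecule_table()].
#' @export
read_molecule_table <- function(path, sample_id) {
  if (!file.exists(path)) stop("molecule file not found: ", path, call. = FALSE)
  if (grepl("\\.(h5|hdf5)$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("reading HDF5 molecule files requires the rhdf5 package", call. = FALSE)
    }
    present <- rhdf5::h5ls(path)$name
    need <- c("cell_barcode", "umi", "gene", "reads")
    missing_ds <- setdiff(need, present)
    if (length(missing_ds)) {
      stop("HDF5 molecule file missing dataset(s): ",
           paste(missing_ds, collapse = ", "), call. = FALSE)
    }
    records <- tibble::tibble(
      cell_barcode = as.character(rhdf5::h5read(path, "cell_barcode")),
      umi = as.character(rhdf5::h5read(path, "umi")),
      gene = as.character(rhdf5::h5read(path, "gene")),
      reads = as.numeric(rhdf5::h5read(path, "reads"))
    )
  } else {
    records <- readr::read_tsv(path, col_types = readr::cols(
      cell_barcode = "c", umi = "c", gene = "c", reads = "d"
    ))
  }
  molecule_table(records, sample_id)
}

#' Write a molecule table to disk
#'
#' Writes the layouts that [read_molecule_table()] reads back: tab-delimited
#' text, or (for paths ending `.h5`/`.hdf5`) four parallel HDF5 datasets.
#'
#' @param table A [molecule_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(table, path) {
  stopifnot(inherits(table, "molecule_table"))
  if (grepl("\\.(h5|hdf5)$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("writing HDF5 molecule files requires the rhdf5 package", call. = FALSE)
    }
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(table$cell_barcode, path, "cell_barcode")
    rhdf5::h5write(table$umi, path, "umi")
    rhdf5::h5write(table$gene, path, "gene")
    rhdf5::h5write(as.integer(table$reads), path, "reads")
    rhdf5::h5closeAll()
  } else {
    readr::write_tsv(as.data.frame(table), path)
  }
  invisible(path)
}

#' Write per-sample UMI count matrices
#'
#' Converts cleaned molecule tables into gene x cell-barcode count matrices —
#' counting distinct molecules (UMIs), not reads — and writes each sample as
#' MatrixMarket `<sample>.mtx` with sidecars `<sample>.genes.txt` and
#' `<sample>.barcodes.txt` under `out_dir`.
#'
#' @param tables A list of [molecule_table()] objects.
#' @param out_dir Output directory (created if needed).
#' @param genes,barcodes Optional character vectors fixing the matrix row /
#'   column universe (shared across samples); defaults to the genes/barcodes
#'   observed in each table.
#' @return Invisibly, a named list of the written matrices.
#' @export
write_cleaned_counts <- function(tables, out_dir, genes = NULL, barcodes = NULL) {
  stopifnot(is.list(tables), all(purrr::map_lgl(tables, inherits, "molecule_table")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mats <- purrr::map(tables, function(tab) {
    g <- genes %||% sort(unique(tab$gene))
    b <- barcodes %||% sort(unique(tab$cell_barcode))
    mat <- Matrix::sparseMatrix(
      i = match(tab$gene, g), j = match(tab$cell_barcode, b),
      x = rep(1, nrow(tab)),  # one distinct molecule per record
      dims = c(length(g), length(b)), dimnames = list(g, b)
    )
    stem <- file.path(out_dir, sample_id(tab))
    Matrix::writeMM(mat, paste0(stem, ".mtx"))
    writeLines(g, paste0(stem, ".genes.txt"))
    writeLines(b, paste0(stem, ".barcodes.txt"))
    mat
  })
  names(mats) <- purrr::map_chr(tables, sample_id)
  invisible(mats)
}
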