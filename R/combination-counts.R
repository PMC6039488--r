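#' Per-combination read counts
#'
#' Holds the mapped-read library size for every row x column barcode
#' combination of a design (expected and impossible), and optionally a
#' gene x combination count matrix whose column sums equal the library sizes.
#'
#' @param design A [plate_design()].
#' @param library_size A data frame with columns `row`, `col`,
#'   `library_size` (non-negative integers). Combinations absent from the
#'   table get library size 0.
#' @param gene_counts Optional gene x combination matrix (base or
#'   [Matrix::Matrix]) with rownames = gene IDs and colnames =
#'   `"<row>:<col>"` combination labels. Column sums must equal the library
#'   sizes of the same combinations.
#'
#' @return A `combination_counts` object: list with elements `design`,
#'   `counts` (tibble `row`, `col`, `expected`, `library_size` covering the
#'   full grid) and `gene_counts` (or `NULL`).
#' @export
combination_counts <- function(design, library_size, gene_counts = NULL) {
  stopifnot(inherits(design, "plate_design"))
  library_size <- tibble::as_tibble(library_size)
  need <- c("row", "col", "library_size")
  if (!all(need %in% names(library_size))) {
    stop("`library_size` needs columns row, col, library_size", call. = FALSE)
  }
  library_size <- library_size[need]
  bad_row <- setdiff(library_size$row, all_row_barcodes(design))
  bad_col <- setdiff(library_size$col, all_col_barcodes(design))
  if (length(bad_row) || length(bad_col)) {
    stop("unknown barcode ID(s) in counts: ",
         paste(c(bad_row, bad_col), collapse = ", "), call. = FALSE)
  }
  key <- paste(library_size$row, library_size$col)
  if (anyDuplicated(key)) {
    stop("duplicated combination(s) in counts: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(is.na(library_size$library_size)) || any(library_size$library_size < 0)) {
    stop("library sizes must be non-negative", call. = FALSE)
  }
  grid <- all_combinations(design)
  counts <- dplyr::left_join(grid, library_size, by = c("row", "col")) |>
    dplyr::mutate(library_size = dplyr::coalesce(.data$library_size, 0)) |>
    dplyr::select("row", "col", "expected", "library_size")

  if (!is.null(gene_counts)) {
    if (is.null(rownames(gene_counts)) || is.null(colnames(gene_counts))) {
      stop("`gene_counts` must have gene rownames and '<row>:<col>' colnames",
           call. = FALSE)
    }
    lab <- combo_label(counts$row, counts$col)
    unknown <- setdiff(colnames(gene_counts), lab)
    if (length(unknown)) {
      stop("gene_counts column(s) not in design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cs <- Matrix::colSums(gene_counts)
    ls <- stats::setNames(counts$library_size, lab)[colnames(gene_counts)]
    if (any(cs != ls)) {
      off <- colnames(gene_counts)[cs != ls][1]
      stop("gene_counts column sum does not match library_size for ", off,
           call. = FALSE)
    }
  }
  structure(
    list(design = design, counts = counts, gene_counts = gene_counts),
    class = "combination_counts"
  )
}

combo_label <- function(row, col) paste(row, col, sep = ":")

#' @export
print.combination_counts <- function(x, ...) {
  n_imp <- sum(!x$counts$expected)
  cat("<combination_counts> ", nrow(x$counts), " combinations (",
      n_imp, " impossible), total reads ",
      format(sum(x$counts$library_size), big.mark = ","), "\n", sep = "")
  if (!is.null(x$gene_counts)) {
    cat("  gene counts: ", nrow(x$gene_counts), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read plate combination counts from disk
#'
#' Two layouts are accepted for `counts_path`:
#' \describe{
#'   \item{delimited text}{a tab-delimited file with header columns
#'     `row`, `col`, `library_size`;}
#'   \item{MatrixMarket}{a `.mtx` gene x combination matrix with sidecar
#'     files `<stem>.genes.txt` (one gene ID per line) and
#'     `<stem>.combinations.tsv` (columns `row`, `col`, one line per matrix
#'     column, in order), where `<stem>` is `counts_path` without the `.mtx`
#'     extension. Library sizes are the column sums.}
#' }
#' Combinations absent from the file get library size 0; barcodes not present
#' in the design are an error.
#'
#' @param design_path Path to a plate design file (see
#'   [read_plate_design()]), or a [plate_design()] object.
#' @param counts_path Path to the counts file.
#' @return A [combination_counts()] object.
#' @export
read_plate_counts <- function(design_path, counts_path) {
  design <- if (inherits(design_path, "plate_design")) design_path
            else read_plate_design(design_path)
  if (!file.exists(counts_path)) {
    stop("counts file not found: ", counts_path, call. = FALSE)
  }
  if (grepl("\\.mtx$", counts_path)) {
    stem <- sub("\\.mtx$", "", counts_path)
    genes <- readLines(paste0(stem, ".genes.txt"))
    combos <- readr::read_tsv(paste0(stem, ".combinations.tsv"),
                              col_types = readr::cols(.default = "c"))
    mat <- as(Matrix::readMM(counts_path), "CsparseMatrix")
    if (nrow(mat) != length(genes) || ncol(mat) != nrow(combos)) {
      stop("MatrixMarket dimensions do not match sidecar files", call. = FALSE)
    }
    rownames(mat) <- genes
    colnames(mat) <- combo_label(combos$row, combos$col)
    ls <- tibble::tibble(row = combos$row, col = combos$col,
                         library_size = unname(Matrix::colSums(mat)))
    combination_counts(design, ls, gene_counts = mat)
  } else {
    tab <- readr::read_tsv(counts_path, col_types = readr::cols(
      row = "c", col = "c", library_size = "d"
    ))
    combination_counts(design, tab)
  }
}

#' Write plate combination counts to disk
#'
#' Writes the layout that [read_plate_counts()] reads: a tab-delimited
#' library-size table (combinations with zero reads are included), and, when
#' gene-level counts are present, a MatrixMarket file with its two sidecars.
#'
#' @param counts A [combination_counts()] object.
#' @param counts_path Output path; use a `.mtx` extension to write the
#'   gene-level layout.
#' @return `counts_path`, invisibly.
#' @export
write_plate_counts <- function(counts, counts_path) {
  stopifnot(inherits(counts, "combination_counts"))
  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(counts$gene_counts)) {
      stop("no gene counts to write as MatrixMarket", call. = FALSE)
    }
    stem <- sub("\\.mtx$", "", counts_path)
    mat <- counts$gene_counts
    Matrix::writeMM(as(as(mat, "dMatrix"), "CsparseMatrix"), counts_path)
    writeLines(rownames(mat), paste0(stem, ".genes.txt"))
    lab <- strsplit(colnames(mat), ":", fixed = TRUE)
    readr::write_tsv(
      tibble::tibble(row = purrr::map_chr(lab, 1), col = purrr::map_chr(lab, 2)),
      paste0(stem, ".combinations.tsv")
    )
  } else {
    readr::write_tsv(
      dplyr::select(counts$counts, "row", "col", "library_size"),
      counts_path
    )
  }
  invisible(counts_path)
}
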