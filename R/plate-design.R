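#' Plate barcode design
#'
#' Describes which row and column sample barcodes were used on each plate of a
#' multiplexed plate-based scRNA-seq experiment. Combinations of a row and a
#' column barcode from the *same* plate are "expected" (a real cell library
#' could carry them); combinations mixing barcodes from *different* plates are
#' "impossible" — no library was ever prepared with them, so any reads observed
#' there must come from barcode swapping or misassignment.
#'
#' Barcode identifiers must be unique across the whole design: a barcode
#' belongs to exactly one plate and one axis. Reusing barcodes between plates
#' would collapse the expected/impossible distinction that the swapped-fraction
#' estimator relies on.
#'
#' @param row_barcodes Named list: plate ID -> character vector of row-barcode
#'   IDs used on that plate.
#' @param col_barcodes Named list: plate ID -> character vector of
#'   column-barcode IDs. Names must match `row_barcodes`.
#'
#' @return A `plate_design` object.
#' @examples
#' design <- plate_design(
#'   row_barcodes = list(P1 = c("R1", "R2"), P2 = c("R3", "R4")),
#'   col_barcodes = list(P1 = c("C1", "C2"), P2 = c("C3", "C4"))
#' )
#' expected_combinations(design)
#' impossible_combinations(design)
#' @export
plate_design <- function(row_barcodes, col_barcodes) {
  if (!is.list(row_barcodes) || !is.list(col_barcodes)) {
    stop("`row_barcodes` and `col_barcodes` must be named lists of character vectors",
         call. = FALSE)
  }
  plates <- names(row_barcodes)
  if (is.null(plates) || any(plates == "") || anyDuplicated(plates)) {
    stop("plate IDs (list names) must be unique and non-empty", call. = FALSE)
  }
  if (!setequal(plates, names(col_barcodes))) {
    stop("`row_barcodes` and `col_barcodes` must name the same plates", call. = FALSE)
  }
  col_barcodes <- col_barcodes[plates]
  row_barcodes <- lapply(row_barcodes, as.character)
  col_barcodes <- lapply(col_barcodes, as.character)
  all_bc <- c(unlist(row_barcodes, use.names = FALSE),
              unlist(col_barcodes, use.names = FALSE))
  if (length(all_bc) == 0 || any(!nzchar(all_bc))) {
    stop("barcode IDs must be non-empty strings", call. = FALSE)
  }
  dup <- unique(all_bc[duplicated(all_bc)])
  if (length(dup) > 0) {
    stop("barcode ID(s) reused across plates or axes: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(
    list(plates = plates, row_barcodes = row_barcodes, col_barcodes = col_barcodes),
    class = "plate_design"
  )
}

#' @export
print.plate_design <- function(x, ...) {
  cat("<plate_design> ", length(x$plates), " plate(s), ",
      sum(lengths(x$row_barcodes)), " row and ",
      sum(lengths(x$col_barcodes)), " column barcodes\n", sep = "")
  for (p in x$plates) {
    cat("  ", p, ": ", length(x$row_barcodes[[p]]), " rows x ",
        length(x$col_barcodes[[p]]), " cols\n", sep = "")
  }
  invisible(x)
}

all_row_barcodes <- function(design) unlist(design$row_barcodes, use.names = FALSE)
all_col_barcodes <- function(design) unlist(design$col_barcodes, use.names = FALSE)

# plate of origin for each barcode, as a named character vector
barcode_plate <- function(design) {
  rows <- design$row_barcodes
  cols <- design$col_barcodes
  stats::setNames(
    rep(design$plates, times = lengths(rows) + lengths(cols)),
    c(unlist(mapply(function(r, c) c(r, c), rows, cols, SIMPLIFY = FALSE),
             use.names = FALSE))
  )[c(all_row_barcodes(design), all_col_barcodes(design))]
}

#' All row/column barcode combinations of a design
#'
#' `all_combinations()` enumerates the full row x column grid across plates and
#' labels each pair as expected (same plate) or impossible (different plates).
#' `expected_combinations()` and `impossible_combinations()` return the
#' respective subsets. The two subsets are disjoint and together cover the
#' whole grid.
#'
#' @param design A [plate_design()].
#' @return A tibble with columns `row`, `col` and (for `all_combinations`)
#'   `expected` (logical) and `plate` (the common plate for expected pairs,
#'   `NA` otherwise).
#' @export
all_combinations <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  rows <- all_row_barcodes(design)
  cols <- all_col_barcodes(design)
  plate_of <- barcode_plate(design)
  grid <- tidyr::expand_grid(row = rows, col = cols)
  same <- plate_of[grid$row] == plate_of[grid$col]
  grid$expected <- unname(same)
  grid$plate <- ifelse(same, unname(plate_of[grid$row]), NA_character_)
  grid
}

#' @rdname all_combinations
#' @export
expected_combinations <- function(design) {
  dplyr::filter(all_combinations(design), .data$expected) |>
    dplyr::select("row", "col", "plate")
}

#' @rdname all_combinations
#' @export
impossible_combinations <- function(design) {
  dplyr::filter(all_combinations(design), !.data$expected) |>
    dplyr::select("row", "col")
}

#' Do two barcode combinations share exactly one barcode?
#'
#' A single barcode swap moves a read between combinations that agree on
#' exactly one of the two barcodes (same row, different column, or vice
#' versa). Vectorised over the second combination.
#'
#' @param row,col Row/column barcode of the reference combination (length 1).
#' @param rows,cols Row/column barcodes of the combinations to compare against
#'   (equal length).
#' @return Logical vector: `TRUE` where exactly one barcode is shared.
#' @export
shares_one_barcode <- function(row, col, rows, cols) {
  stopifnot(length(row) == 1, length(col) == 1, length(rows) == length(cols))
  xor(rows == row, cols == col)
}

#' Read or write a plate design file
#'
#' The file is tab-delimited with three columns and a header:
#' `plate`, `axis` (`row` or `col`) and `barcodes` (comma-separated barcode
#' IDs, in plate order). One line per plate and axis.
#'
#' @param path File path.
#' @param design A [plate_design()] (for writing).
#' @return `read_plate_design()` returns a `plate_design`;
#'   `write_plate_design()` returns `path` invisibly.
#' @export
read_plate_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("plate", "axis", "barcodes")
  if (!all(need %in% names(tab))) {
    stop("design file must have columns plate, axis, barcodes", call. = FALSE)
  }
  if (!all(tab$axis %in% c("row", "col"))) {
    stop("design file axis must be 'row' or 'col'", call. = FALSE)
  }
  split_bc <- function(axis) {
    sub <- tab[tab$axis == axis, ]
    stats::setNames(lapply(strsplit(sub$barcodes, ","), trimws), sub$plate)
  }
  plate_design(row_barcodes = split_bc("row"), col_barcodes = split_bc("col"))
}

#' @rdname read_plate_design
#' @export
write_plate_design <- function(design, path) {
  stopifnot(inherits(design, "plate_design"))
  rows <- tibble::tibble(
    plate = design$plates, axis = "row",
    barcodes = purrr::map_chr(design$row_barcodes, paste, collapse = ",")
  )
  cols <- tibble::tibble(
    plate = design$plates, axis = "col",
    barcodes = purrr::map_chr(design$col_barcodes, paste, collapse = ",")
  )
  readr::write_tsv(dplyr::bind_rows(rows, cols), path)
  invisible(path)
}
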