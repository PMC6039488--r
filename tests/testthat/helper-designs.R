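# Small plate designs and count builders shared across tests.

toy_design <- function() {
  plate_design(
    row_barcodes = list(P1 = c("R1", "R2"), P2 = c("R3", "R4")),
    col_barcodes = list(P1 = c("C1", "C2"), P2 = c("C3", "C4"))
  )
}

# the two-96-well-plate layout: 8 rows x 12 columns per plate, no reuse
two_plate_design <- function(n_rows = 8, n_cols = 12) {
  plate_design(
    row_barcodes = list(
      P1 = sprintf("R%02d", seq_len(n_rows)),
      P2 = sprintf("R%02d", n_rows + seq_len(n_rows))
    ),
    col_barcodes = list(
      P1 = sprintf("C%02d", seq_len(n_cols)),
      P2 = sprintf("C%02d", n_cols + seq_len(n_cols))
    )
  )
}

# combination_counts with the given library size in every expected combination
uniform_counts <- function(design, value = 10) {
  exp_tab <- expected_combinations(design)
  combination_counts(
    design,
    tibble::tibble(row = exp_tab$row, col = exp_tab$col, library_size = value)
  )
}

# counts where each impossible combination holds exactly `rate` x its
# available reads (expected sizes supplied, possibly varying)
exact_linear_counts <- function(design, expected_sizes, rate) {
  exp_tab <- expected_combinations(design)
  stopifnot(length(expected_sizes) == nrow(exp_tab))
  base <- combination_counts(
    design,
    tibble::tibble(row = exp_tab$row, col = exp_tab$col,
                   library_size = expected_sizes)
  )
  dat <- impossible_regression_data(base)
  all_ls <- dplyr::bind_rows(
    tibble::tibble(row = exp_tab$row, col = exp_tab$col,
                   library_size = expected_sizes),
    tibble::tibble(row = dat$row, col = dat$col,
                   library_size = rate * dat$available)
  )
  combination_counts(design, all_ls)
}

mol_tab <- function(id, ...) {
  molecule_table(tibble::tibble(...), sample_id = id)
}
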