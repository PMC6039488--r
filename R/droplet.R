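#' Test samples for excess cell-barcode sharing
#'
#' Cell barcodes are drawn independently in each droplet sample from a large
#' common pool, so some sharing between multiplexed samples is expected by
#' chance. Barcode swapping inflates it: swapped molecules carry their donor's
#' cell barcode into the recipient sample. For every unordered sample pair
#' this computes the observed overlap and the upper-tail hypergeometric
#' probability of an overlap at least that large — population `pool_size`,
#' draws `|A|`, successes `|B|` — i.e. `P(X >= k)` evaluated as the survival
#' function at `k - 1`. P-values are Benjamini-Hochberg adjusted across pairs.
#'
#' @param barcode_sets Named list: sample ID -> character vector of observed
#'   cell barcodes (or a list of [molecule_table()] objects, whose barcodes
#'   are extracted).
#' @param pool_size Number of possible cell barcodes. Defaults to the standard
#'   10x whitelist size, 737,280. `NULL` conditions on the union of observed
#'   barcodes instead of an explicit pool.
#' @return A `sharing_result` tibble: one line per pair with columns
#'   `sample_a`, `sample_b`, `n_a`, `n_b`, `overlap`, `pool_size`, `p_value`,
#'   `adjusted_p`.
#' @export
sharing_test <- function(barcode_sets, pool_size = 737280) {
  if (all(purrr::map_lgl(barcode_sets, inherits, "molecule_table"))) {
    names(barcode_sets) <- purrr::map_chr(barcode_sets, sample_id)
    barcode_sets <- purrr::map(barcode_sets, ~ unique(.x$cell_barcode))
  }
  stopifnot(is.list(barcode_sets), length(barcode_sets) >= 2)
  if (is.null(names(barcode_sets)) || anyDuplicated(names(barcode_sets))) {
    stop("`barcode_sets` must be uniquely named by sample", call. = FALSE)
  }
  sets <- purrr::map(barcode_sets, unique)
  if (is.null(pool_size)) {
    pool_size <- length(unique(unlist(sets, use.names = FALSE)))
  }
  if (any(lengths(sets) > pool_size)) {
    stop("a sample has more barcodes than the pool size", call. = FALSE)
  }
  ids <- names(sets)
  pairs <- utils::combn(ids, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    k <- length(intersect(sets[[a]], sets[[b]]))
    tibble::tibble(
      sample_a = a, sample_b = b,
      n_a = length(sets[[a]]), n_b = length(sets[[b]]),
      overlap = k, pool_size = pool_size,
      p_value = phyper(k - 1, length(sets[[b]]),
                       pool_size - length(sets[[b]]),
                       length(sets[[a]]), lower.tail = FALSE)
    )
  })
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  class(res) <- c("sharing_result", class(res))
  res
}

#' Expected cost of excluding shared cell barcodes
#'
#' If swapping is handled by discarding every cell barcode observed in more
#' than one multiplexed sample, real cells are lost to chance collisions. For
#' `S` samples each drawing `c` barcodes without replacement from a pool of
#' `N`, the probability that a given barcode drawn in one sample also appears
#' in at least one of the other `S - 1` (independent) samples is
#' `1 - (1 - c/N)^(S - 1)`: the expected excluded fraction of cell libraries.
#'
#' @param n_samples Number of multiplexed samples `S`.
#' @param cells_per_sample Cells captured per sample `c`.
#' @param pool_size Barcode pool size `N` (default: 10x whitelist, 737,280).
#' @return The expected excluded fraction, in \[0, 1\].
#' @examples
#' expected_exclusion_fraction(30, 20000)  # > 0.5
#' @export
expected_exclusion_fraction <- function(n_samples, cells_per_sample,
                                        pool_size = 737280) {
  stopifnot(n_samples >= 1, cells_per_sample >= 1,
            cells_per_sample <= pool_size)
  1 - (1 - cells_per_sample / pool_size)^(n_samples - 1)
}

#' Monte-Carlo simulation of the cell-exclusion cost
#'
#' Draws `cells_per_sample` barcodes without replacement per sample,
#' independently across `n_samples` samples, and counts the fraction of
#' barcode draws (cell libraries) whose barcode occurs in two or more
#' samples. Repeated `n_reps` times; reports the mean and its Monte-Carlo
#' standard error.
#'
#' @inheritParams expected_exclusion_fraction
#' @param n_reps Number of independent repetitions.
#' @param seed Optional seed, applied locally.
#' @return A tibble with one row: `excluded_fraction`, `mc_std_error`,
#'   `n_reps`, plus the model parameters.
#' @export
simulate_cell_exclusion <- function(n_samples, cells_per_sample,
                                    pool_size = 737280, n_reps = 10,
                                    seed = NULL) {
  stopifnot(n_samples >= 1, cells_per_sample >= 1,
            cells_per_sample <= pool_size, n_reps >= 1)
  fracs <- with_local_seed(seed, {
    purrr::map_dbl(seq_len(n_reps), function(r) {
      draws <- unlist(lapply(seq_len(n_samples), function(s) {
        sample.int(pool_size, cells_per_sample)
      }), use.names = FALSE)
      # within a sample draws are distinct, so multiplicity >= 2 in the pooled
      # tally means the barcode occurs in >= 2 samples
      tab <- tabulate(draws)
      mult <- tab[draws]
      mean(mult >= 2)
    })
  })
  tibble::tibble(
    excluded_fraction = mean(fracs),
    mc_std_error = if (n_reps > 1) stats::sd(fracs) / sqrt(n_reps) else NA_real_,
    n_reps = n_reps,
    n_samples = n_samples,
    cells_per_sample = cells_per_sample,
    pool_size = pool_size
  )
}

#' Remove swapped molecules from multiplexed droplet samples
#'
#' Molecules observed in different samples with the same (cell barcode, UMI,
#' gene) key are almost certainly copies of one true molecule spread by
#' barcode swapping — chance triple collisions are combinatorially rare.
#' For each key observed in more than one sample, the fraction of its reads
#' in each sample is computed: if one sample holds at least `min_frac` of the
#' reads it is taken as the sample of origin and the molecule is removed from
#' all *other* samples; otherwise the origin is ambiguous and the molecule is
#' removed from *all* samples. Keys seen in a single sample are retained
#' unchanged.
#'
#' `min_frac` must exceed 0.5, which guarantees at most one sample can reach
#' it: two samples with read fractions both >= min_frac > 0.5 would sum to
#' more than 1. No tie-breaking is therefore needed.
#'
#' @param tables List of [molecule_table()] objects with distinct sample IDs
#'   (at least two).
#' @param min_frac Minimum read fraction for a sample to be called the origin
#'   of a shared molecule; in (0.5, 1], default 0.8.
#' @return A list with elements `tables` (the cleaned molecule tables, same
#'   order and sample IDs as the input) and `report` (a `cleaning_report`
#'   tibble: per sample, molecules in/retained/removed as swapped-in/removed
#'   as unresolved, with the number of multi-sample key groups and `min_frac`
#'   as attributes).
#' @export
remove_swapped_molecules <- function(tables, min_frac = 0.8) {
  stopifnot(is.list(tables), length(tables) >= 2,
            all(purrr::map_lgl(tables, inherits, "molecule_table")))
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0.5 || min_frac > 1) {
    stop("`min_frac` must be in (0.5, 1]: values <= 0.5 would let two samples ",
         "both claim a molecule", call. = FALSE)
  }
  ids <- purrr::map_chr(tables, sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  combined <- dplyr::bind_rows(
    purrr::map2(tables, ids, function(tab, id) {
      dplyr::mutate(tibble::as_tibble(tab), .sample = id)
    })
  )
  if (nrow(combined) == 0) {
    report <- tibble::tibble(
      sample = ids, molecules_in = 0L, retained = 0L,
      removed_swapped = 0L, removed_unresolved = 0L
    )
    return(cleaning_result(tables, report, 0L, min_frac))
  }
  # dense integer ids per (cell_barcode, umi, gene) key; vectorised per-group
  # totals and maxima (a key appears at most once per sample, so multiplicity
  # equals the number of samples holding it)
  gid <- vctrs::vec_group_id(combined[c("cell_barcode", "umi", "gene")])
  n_in_group <- tabulate(gid)
  total <- rowsum(combined$reads, gid)[, 1]
  ord <- order(gid, -combined$reads)
  grp_max <- combined$reads[ord][!duplicated(gid[ord])]
  shared <- n_in_group[gid] > 1
  unresolved <- shared & grp_max[gid] / total[gid] < min_frac
  # in a resolved group the argmax is unique: two samples at the maximum would
  # each hold <= 1/2 < min_frac of the reads
  is_max <- combined$reads == grp_max[gid]
  status <- dplyr::case_when(
    !shared ~ "retained",
    unresolved ~ "removed_unresolved",
    is_max ~ "retained",
    TRUE ~ "removed_swapped"
  )
  tally <- function(st) {
    as.integer(table(factor(combined$.sample[status == st], levels = ids)))
  }
  report <- tibble::tibble(
    sample = ids,
    molecules_in = as.integer(table(factor(combined$.sample, levels = ids))),
    retained = tally("retained"),
    removed_swapped = tally("removed_swapped"),
    removed_unresolved = tally("removed_unresolved")
  )
  kept <- combined[status == "retained", ]
  cleaned <- purrr::map(ids, function(id) {
    sub <- kept[kept$.sample == id,
                c("cell_barcode", "umi", "gene", "reads")]
    new_molecule_table(sub, id)
  })
  cleaning_result(cleaned, report,
                  n_multi_groups = length(unique(gid[shared])),
                  min_frac = min_frac)
}

cleaning_result <- function(tables, report, n_multi_groups, min_frac) {
  attr(report, "n_multi_sample_groups") <- n_multi_groups
  attr(report, "min_frac") <- min_frac
  class(report) <- c("cleaning_report", class(report))
  list(tables = tables, report = report)
}

#' Call cells by a UMI-count threshold
#'
#' Returns the cell barcodes supported by at least `min_umis` distinct
#' molecules (UMIs, not reads). A deliberately simple stand-in for
#' ambient-aware cell callers, sufficient to demonstrate artefactual
#' libraries appearing and disappearing around cleaning.
#'
#' @param table A [molecule_table()].
#' @param min_umis Minimum number of distinct molecules (default 1000).
#' @return Character vector of called cell barcodes.
#' @export
call_cells_threshold <- function(table, min_umis = 1000) {
  stopifnot(inherits(table, "molecule_table"), min_umis >= 1)
  if (nrow(table) == 0) return(character(0))
  per_bc <- dplyr::count(tibble::as_tibble(table), .data$cell_barcode)
  per_bc$cell_barcode[per_bc$n >= min_umis]
}
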