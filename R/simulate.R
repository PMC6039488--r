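#' Simulate a plate experiment with known barcode swapping
#'
#' Generates library sizes for every expected combination of a design from a
#' negative-binomial model, then pushes each read through the swapping
#' mechanism: with probability `swap_fraction` a read swaps, picking one of
#' its two barcodes with equal probability and replacing it with a uniformly
#' chosen *other* barcode of the same axis (any plate). Swapped reads land in
#' expected or impossible combinations accordingly; total reads are conserved.
#'
#' Optionally, reads within each combination are spread over `genes` genes
#' (multinomial over fixed lognormal gene weights), yielding gene-level
#' counts whose column sums equal the library sizes.
#'
#' @param design A [plate_design()].
#' @param mean_reads Mean reads per expected combination.
#' @param dispersion Negative-binomial size parameter of the library-size
#'   model (larger = less variable).
#' @param swap_fraction Per-read swapping probability `f`, in \[0, 1).
#' @param genes Number of genes for optional gene-level counts, or `NULL`
#'   (default) for library sizes only.
#' @param seed Optional seed, applied locally.
#' @return A list: `counts` (a [combination_counts()] of the observed reads),
#'   `truth` (tibble of true pre-swap library sizes per expected combination),
#'   `swapped_reads` (number of reads that swapped) and `realised_fraction`
#'   (swapped reads over total reads).
#' @export
simulate_plate <- function(design, mean_reads = 5000, dispersion = 5,
                           swap_fraction = 0.02, genes = NULL, seed = NULL) {
  stopifnot(inherits(design, "plate_design"),
            swap_fraction >= 0, swap_fraction < 1,
            mean_reads > 0, dispersion > 0)
  rows <- all_row_barcodes(design)
  cols <- all_col_barcodes(design)
  with_local_seed(seed, {
    exp_tab <- expected_combinations(design)
    truth <- rnbinom(nrow(exp_tab), mu = mean_reads, size = dispersion)
    # observed read tally over the full grid
    obs <- matrix(0, nrow = length(rows), ncol = length(cols),
                  dimnames = list(rows, cols))
    n_swap <- rbinom(nrow(exp_tab), truth, swap_fraction)
    n_row_axis <- rbinom(nrow(exp_tab), n_swap, 0.5)
    for (i in seq_len(nrow(exp_tab))) {
      r <- exp_tab$row[i]; c <- exp_tab$col[i]
      obs[r, c] <- obs[r, c] + truth[i] - n_swap[i]
      if (n_row_axis[i] > 0) {
        dest_r <- setdiff(rows, r)
        arr <- stats::rmultinom(1, n_row_axis[i],
                                rep(1 / length(dest_r), length(dest_r)))[, 1]
        obs[dest_r, c] <- obs[dest_r, c] + arr
      }
      n_col_axis <- n_swap[i] - n_row_axis[i]
      if (n_col_axis > 0) {
        dest_c <- setdiff(cols, c)
        arr <- stats::rmultinom(1, n_col_axis,
                                rep(1 / length(dest_c), length(dest_c)))[, 1]
        obs[r, dest_c] <- obs[r, dest_c] + arr
      }
    }
    ls <- tibble::tibble(
      row = rep(rows, times = length(cols)),
      col = rep(cols, each = length(rows)),
      library_size = as.vector(obs)
    )
    gene_counts <- NULL
    if (!is.null(genes)) {
      w <- stats::rlnorm(genes, sdlog = 1)
      w <- w / sum(w)
      nonzero <- ls$library_size > 0
      gm <- matrix(0L, nrow = genes, ncol = nrow(ls),
                   dimnames = list(sprintf("G%04d", seq_len(genes)),
                                   combo_label(ls$row, ls$col)))
      gm[, nonzero] <- vapply(which(nonzero), function(j) {
        stats::rmultinom(1, ls$library_size[j], w)[, 1]
      }, integer(genes))
      gene_counts <- gm
    }
    list(
      counts = combination_counts(design, ls, gene_counts = gene_counts),
      truth = dplyr::bind_cols(exp_tab[c("row", "col")],
                               tibble::tibble(true_reads = truth)),
      swapped_reads = sum(n_swap),
      realised_fraction = if (sum(truth) > 0) sum(n_swap) / sum(truth) else 0
    )
  })
}

#' Simulate a plate sequenced on two platforms
#'
#' Generates a true gene x cell count matrix for a single plate
#' (`n_rows` x `n_cols` cells, exchangeable negative-binomial expression over
#' lognormal gene weights), then produces two sequencing images of it: a
#' reference platform with swap rate `ref_swap_fraction` (default 0, the
#' non-patterned flow-cell role) and a swapping-affected platform with rate
#' `swap_fraction`. Swapping moves a read to a cell sharing exactly one
#' barcode: the swapped read keeps its gene, picks row or column barcode with
#' equal probability, and lands uniformly on one of the other barcodes of
#' that axis within the plate.
#'
#' @param n_rows,n_cols Plate dimensions (cells are the full grid).
#' @param genes Number of genes.
#' @param mean_reads_per_cell Mean total reads per cell.
#' @param dispersion Negative-binomial size of per-gene counts.
#' @param swap_fraction Per-read swap probability on the affected platform.
#' @param ref_swap_fraction Per-read swap probability on the reference
#'   platform (default 0).
#' @param seed Optional seed, applied locally.
#' @return A [cross_platform_pair()]; the true (pre-swap) matrix is attached
#'   as attribute `"truth"`.
#' @export
simulate_crossplatform <- function(n_rows = 8, n_cols = 12, genes = 200,
                                   mean_reads_per_cell = 10000,
                                   dispersion = 2, swap_fraction = 0.02,
                                   ref_swap_fraction = 0, seed = NULL) {
  stopifnot(n_rows >= 2, n_cols >= 2, genes >= 1,
            swap_fraction >= 0, swap_fraction < 1,
            ref_swap_fraction >= 0, ref_swap_fraction < 1)
  with_local_seed(seed, {
    rows <- sprintf("R%02d", seq_len(n_rows))
    cols <- sprintf("C%02d", seq_len(n_cols))
    cells <- tidyr::expand_grid(col = cols, row = rows)
    lab <- combo_label(cells$row, cells$col)
    w <- stats::rlnorm(genes, sdlog = 1.5)
    mu <- mean_reads_per_cell * w / sum(w)
    truth <- matrix(
      rnbinom(genes * nrow(cells), mu = rep(mu, nrow(cells)), size = dispersion),
      nrow = genes, dimnames = list(sprintf("G%04d", seq_len(genes)), lab)
    )
    swap_reads <- function(mat, f) {
      if (f == 0) return(mat)
      n_swap <- matrix(rbinom(length(mat), mat, f), nrow = nrow(mat),
                       dimnames = dimnames(mat))
      out <- mat - n_swap
      sw <- which(n_swap > 0, arr.ind = TRUE)
      if (nrow(sw) > 0) {
        # one row per swapped read: (gene, origin cell)
        counts <- n_swap[sw]
        g_idx <- rep(sw[, 1], counts)
        c_idx <- rep(sw[, 2], counts)
        axis_row <- stats::runif(length(g_idx)) < 0.5
        o_row <- match(cells$row[c_idx], rows)
        o_col <- match(cells$col[c_idx], cols)
        # uniform over the other barcodes of the chosen axis
        d_row <- ifelse(
          axis_row,
          (o_row - 1 + sample.int(n_rows - 1, length(g_idx), replace = TRUE)) %%
            n_rows + 1,
          o_row
        )
        d_col <- ifelse(
          axis_row,
          o_col,
          (o_col - 1 + sample.int(n_cols - 1, length(g_idx), replace = TRUE)) %%
            n_cols + 1
        )
        d_cell <- (d_col - 1) * n_rows + d_row  # cells are col-major over the grid
        arrivals <- Matrix::sparseMatrix(
          i = g_idx, j = d_cell, x = 1,
          dims = dim(mat)
        )
        out <- out + as.matrix(arrivals)
      }
      out
    }
    pair <- cross_platform_pair(
      counts_ref = swap_reads(truth, ref_swap_fraction),
      counts_swapped = swap_reads(truth, swap_fraction)
    )
    attr(pair, "truth") <- truth
    pair
  })
}

#' Simulate multiplexed droplet samples with known barcode swapping
#'
#' Each of `n_samples` samples draws `cells_per_sample` cell barcodes without
#' replacement from a shared pool of `pool_size`, generates molecules per cell
#' (negative-binomial molecule counts; uniform genes; random UMIs) with read
#' counts (1 + Poisson), then pushes reads through the swapping mechanism:
#' each read independently swaps its *sample* label with probability
#' `swap_fraction`, landing uniformly on one of the other samples, keeping
#' its (cell barcode, UMI, gene) key intact — the cell barcode never swaps.
#' Reads are re-aggregated into per-sample molecule records.
#'
#' Optionally a fraction of sample 1's cells are planted as "donor-only large
#' cells": their barcodes are guaranteed absent from all other samples and
#' their molecule counts are multiplied by `large_factor`, the scenario that
#' produces artefactual cell libraries in recipient samples.
#'
#' @param n_samples Number of multiplexed samples (>= 2 for swapping to have
#'   anywhere to go).
#' @param cells_per_sample Cells per sample.
#' @param pool_size Size of the shared cell-barcode pool.
#' @param genes Number of genes.
#' @param mean_molecules,mol_dispersion Negative-binomial mean and size of
#'   molecules per cell.
#' @param mean_reads Mean reads per molecule (>= 1; reads are
#'   1 + Poisson(mean_reads - 1)).
#' @param swap_fraction Per-read sample-label swap probability.
#' @param donor_large_frac Fraction of sample 1's cells planted as donor-only
#'   large cells (default 0).
#' @param large_factor Molecule-count multiplier for planted large cells.
#' @param umi_length UMI length in bases (default 10); collisions are allowed
#'   and simply produce shared keys, as in real data.
#' @param seed Optional seed, applied locally.
#' @return A list: `tables` (per-sample [molecule_table()]s), `truth` (tibble
#'   with one line per output record: `sample`, key columns, `reads`,
#'   `origin` sample and `swapped_in` flag), `cells` (tibble of true cell
#'   barcodes per sample with `large_donor` flags) and the realised swapped
#'   read fraction.
#' @export
simulate_droplet <- function(n_samples = 4, cells_per_sample = 2000,
                             pool_size = 737280, genes = 500,
                             mean_molecules = 50, mol_dispersion = 2,
                             mean_reads = 20, swap_fraction = 0.02,
                             donor_large_frac = 0, large_factor = 20,
                             umi_length = 10, seed = NULL) {
  stopifnot(n_samples >= 2, cells_per_sample >= 1,
            cells_per_sample <= pool_size, genes >= 1,
            mean_reads >= 1, swap_fraction >= 0, swap_fraction < 1,
            donor_large_frac >= 0, donor_large_frac <= 1)
  with_local_seed(seed, {
    sample_ids <- sprintf("S%d", seq_len(n_samples))
    n_large <- round(donor_large_frac * cells_per_sample)
    bc_idx <- vector("list", n_samples)
    bc_idx[[1]] <- sample.int(pool_size, cells_per_sample)
    large_set <- bc_idx[[1]][seq_len(n_large)]
    rest <- if (n_large > 0) seq_len(pool_size)[-large_set] else NULL
    for (s in seq_len(n_samples)[-1]) {
      bc_idx[[s]] <- if (is.null(rest)) sample.int(pool_size, cells_per_sample)
                     else sample(rest, cells_per_sample)
    }
    cells <- purrr::map_dfr(seq_len(n_samples), function(s) {
      tibble::tibble(
        sample = sample_ids[s],
        cell_barcode = sprintf("BC%07d", bc_idx[[s]]),
        large_donor = s == 1 & bc_idx[[s]] %in% large_set
      )
    })
    mu <- ifelse(cells$large_donor, mean_molecules * large_factor,
                 mean_molecules)
    n_mol <- rnbinom(nrow(cells), mu = mu, size = mol_dispersion)
    cell_of <- rep(seq_len(nrow(cells)), n_mol)
    M <- length(cell_of)
    umi_codes <- sample.int(4^umi_length, M, replace = TRUE)
    mols <- tibble::tibble(
      origin = cells$sample[cell_of],
      cell_barcode = cells$cell_barcode[cell_of],
      umi = encode_umi(umi_codes, umi_length),
      gene = sprintf("G%04d", sample.int(genes, M, replace = TRUE)),
      reads = 1L + rpois(M, mean_reads - 1)
    )
    n_swap <- rbinom(M, mols$reads, swap_fraction)
    # native residue of each molecule
    native <- dplyr::mutate(mols, sample = .data$origin,
                            reads = .data$reads - n_swap)
    # swapped reads, each landing uniformly on one of the other samples
    sw_mol <- rep(seq_len(M), n_swap)
    if (length(sw_mol) > 0) {
      o_idx <- match(mols$origin[sw_mol], sample_ids)
      d_idx <- (o_idx - 1 +
                sample.int(n_samples - 1, length(sw_mol), replace = TRUE)) %%
               n_samples + 1
      swapped <- tibble::tibble(
        origin = mols$origin[sw_mol],
        cell_barcode = mols$cell_barcode[sw_mol],
        umi = mols$umi[sw_mol],
        gene = mols$gene[sw_mol],
        sample = sample_ids[d_idx],
        reads = 1L
      )
    } else {
      swapped <- native[0, ]
    }
    all_reads <- dplyr::bind_rows(native[native$reads > 0, ], swapped)
    # aggregate per (sample, key, origin); group ids are dense integers so
    # rowsum() indexes directly
    gid <- vctrs::vec_group_id(
      all_reads[c("sample", "cell_barcode", "umi", "gene", "origin")]
    )
    sums <- rowsum(all_reads$reads, gid)[, 1]
    first_idx <- which(!duplicated(gid))
    agg <- all_reads[first_idx, ]
    agg$reads <- sums[gid[first_idx]]
    # one output record per (sample, key); origin = majority-read contributor
    gid2 <- vctrs::vec_group_id(
      agg[c("sample", "cell_barcode", "umi", "gene")]
    )
    sums2 <- rowsum(agg$reads, gid2)[, 1]
    ord <- order(gid2, -agg$reads)
    first2 <- ord[!duplicated(gid2[ord])]
    truth <- agg[first2, c("sample", "cell_barcode", "umi", "gene", "origin")]
    truth$reads <- sums2[gid2[first2]]
    truth$swapped_in <- truth$sample != truth$origin
    truth <- tibble::as_tibble(truth)
    tables <- purrr::map(sample_ids, function(id) {
      sub <- truth[truth$sample == id,
                   c("cell_barcode", "umi", "gene", "reads")]
      new_molecule_table(sub, id)
    })
    list(
      tables = tables,
      truth = truth,
      cells = cells,
      realised_fraction = if (sum(mols$reads) > 0) {
        sum(n_swap) / sum(mols$reads)
      } else 0
    )
  })
}

# integer codes 1..4^len -> UMI strings over ACGT
encode_umi <- function(codes, len) {
  codes <- codes - 1
  bases <- c("A", "C", "G", "T")
  pos <- vector("list", len)
  for (p in seq_len(len)) {
    pos[[p]] <- bases[codes %% 4 + 1]
    codes <- codes %/% 4
  }
  do.call(paste0, pos)
}
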