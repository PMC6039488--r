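test_that("hypergeometric sharing p-value matches exhaustive enumeration", {
  # N = 10, |A| = |B| = 5: enumerate all C(10,5) positions of A against a
  # fixed B and tally overlap sizes
  sets <- list(A = sprintf("b%d", 1:5), B = sprintf("b%d", 1:5))
  res <- sharing_test(sets, pool_size = 10)
  expect_equal(res$overlap, 5)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  # full distribution vs enumeration
  positions <- utils::combn(10, 5)
  overlaps <- colSums(positions <= 5)  # B occupies slots 1..5
  for (k in 0:5) {
    expect_equal(
      phyper(k - 1, 5, 5, 5, lower.tail = FALSE),
      mean(overlaps >= k),
      tolerance = 1e-12
    )
  }
})

test_that("zero overlap gives p = 1 and oversize sets are rejected", {
  res <- sharing_test(list(A = c("x", "y"), B = c("z", "w")), pool_size = 10)
  expect_equal(res$p_value, 1)
  expect_equal(res$adjusted_p, 1)
  expect_error(
    sharing_test(list(A = letters[1:5], B = letters[1:2]), pool_size = 4),
    "pool size"
  )
})

test_that("sharing p-values are roughly uniform for independent samples", {
  set.seed(77)
  p <- replicate(60, {
    sets <- list(
      A = as.character(sample.int(5000, 300)),
      B = as.character(sample.int(5000, 300))
    )
    sharing_test(sets, pool_size = 5000)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("expected exclusion fraction has the right boundary behaviour", {
  expect_equal(expected_exclusion_fraction(1, 100), 0)
  expect_equal(expected_exclusion_fraction(2, 50, pool_size = 50), 1)
  # 30 samples of 20,000 cells from the whitelist pool: above one half
  f <- expected_exclusion_fraction(30, 20000, 737280)
  expect_gt(f, 0.5)
  expect_equal(f, 1 - (1 - 20000 / 737280)^29)
})

test_that("simulated exclusion agrees with the closed form", {
  sim <- simulate_cell_exclusion(5, 200, pool_size = 2000, n_reps = 20,
                                 seed = 4)
  expect_lt(
    abs(sim$excluded_fraction - expected_exclusion_fraction(5, 200, 2000)),
    3 * sim$mc_std_error
  )
  # single sample never collides
  sim1 <- simulate_cell_exclusion(1, 50, pool_size = 100, n_reps = 5, seed = 1)
  expect_equal(sim1$excluded_fraction, 0)
  # S = 2, c = 1, N = 2: the two draws agree half the time
  sim2 <- simulate_cell_exclusion(2, 1, pool_size = 2, n_reps = 400, seed = 2)
  expect_equal(sim2$excluded_fraction, 0.5, tolerance = 0.15)
})

test_that("the majority-read rule assigns and removes shared molecules", {
  a <- mol_tab("A", cell_barcode = c("B1", "B2", "B3"),
               umi = c("U1", "U2", "U3"), gene = c("G1", "G2", "G3"),
               reads = c(8, 5, 7))
  b <- mol_tab("B", cell_barcode = c("B1", "B2"), umi = c("U1", "U2"),
               gene = c("G1", "G2"), reads = c(2, 5))
  out <- remove_swapped_molecules(list(a, b), min_frac = 0.8)
  keyA <- paste(out$tables[[1]]$cell_barcode, out$tables[[1]]$umi)
  keyB <- paste(out$tables[[2]]$cell_barcode, out$tables[[2]]$umi)
  # 8 vs 2 reads: exactly at the >= 0.8 boundary, kept in A only
  expect_true("B1 U1" %in% keyA)
  expect_false("B1 U1" %in% keyB)
  # 5 vs 5: no majority, removed from both
  expect_false("B2 U2" %in% keyA)
  expect_false("B2 U2" %in% keyB)
  # single-sample molecule retained untouched
  expect_true("B3 U3" %in% keyA)
  rep_tab <- tibble::as_tibble(out$report)
  expect_equal(rep_tab$molecules_in,
               rep_tab$retained + rep_tab$removed_swapped +
                 rep_tab$removed_unresolved)
  expect_equal(attr(out$report, "n_multi_sample_groups"), 2L)
})

test_that("cleaning conserves molecules, is idempotent and equivariant", {
  sim <- simulate_droplet(n_samples = 3, cells_per_sample = 60,
                          pool_size = 500, genes = 40, mean_molecules = 20,
                          mean_reads = 10, swap_fraction = 0.05, seed = 12)
  out <- remove_swapped_molecules(sim$tables)
  rep_tab <- tibble::as_tibble(out$report)
  # conservation and read values untouched
  expect_equal(rep_tab$molecules_in, purrr::map_int(sim$tables, nrow))
  expect_equal(rep_tab$retained, purrr::map_int(out$tables, nrow))
  for (i in seq_along(out$tables)) {
    orig <- tibble::as_tibble(sim$tables[[i]])
    kept <- tibble::as_tibble(out$tables[[i]])
    merged <- dplyr::inner_join(kept, orig,
                                by = c("cell_barcode", "umi", "gene"))
    expect_equal(nrow(merged), nrow(kept))
    expect_equal(merged$reads.x, merged$reads.y)
  }
  # idempotence
  again <- remove_swapped_molecules(out$tables)
  expect_equal(
    purrr::map(again$tables, tibble::as_tibble),
    purrr::map(out$tables, tibble::as_tibble)
  )
  # permutation equivariance
  perm <- c(3, 1, 2)
  out_perm <- remove_swapped_molecules(sim$tables[perm])
  expect_equal(
    purrr::map(out_perm$tables, tibble::as_tibble),
    purrr::map(out$tables[perm], tibble::as_tibble)
  )
})

test_that("min_frac = 1 removes every shared molecule short of unanimity", {
  # brute force over all two-sample read splits up to 6 reads
  for (ra in 0:6) {
    for (rb in 0:6) {
      if (ra + rb == 0 || (ra == 0 && rb == 0)) next
      recs <- list()
      if (ra > 0) recs$A <- mol_tab("A", cell_barcode = "B", umi = "U",
                                    gene = "G", reads = ra)
      if (rb > 0) recs$B <- mol_tab("B", cell_barcode = "B", umi = "U",
                                    gene = "G", reads = rb)
      if (length(recs) < 2) {
        recs$pad <- mol_tab(setdiff(c("A", "B"), names(recs)),
                            cell_barcode = "Z", umi = "Z", gene = "Z",
                            reads = 1)
      }
      out <- remove_swapped_molecules(unname(recs), min_frac = 1)
      kept <- sum(purrr::map_int(out$tables, function(t) {
        sum(t$cell_barcode == "B")
      }))
      if (ra == 0 || rb == 0) {
        expect_equal(kept, 1)  # one sample holds literally all reads
      } else {
        expect_equal(kept, 0)
      }
    }
  }
})

test_that("invalid cleaning arguments are rejected", {
  a <- mol_tab("A", cell_barcode = "B1", umi = "U1", gene = "G1", reads = 1)
  expect_error(remove_swapped_molecules(list(a, a)), "duplicate")
  b <- mol_tab("B", cell_barcode = "B1", umi = "U1", gene = "G1", reads = 1)
  expect_error(remove_swapped_molecules(list(a, b), min_frac = 0.5), "0.5")
  expect_error(remove_swapped_molecules(list(a)), "length")
})

test_that("cell calling applies a strict UMI threshold", {
  tab <- mol_tab("A",
    cell_barcode = c(rep("big", 1000), rep("small", 999)),
    umi = sprintf("U%04d", c(1:1000, 1:999)),
    gene = "G1",
    reads = 1
  )
  expect_equal(call_cells_threshold(tab, min_umis = 1000), "big")
  empty <- molecule_table(
    tibble::tibble(cell_barcode = character(), umi = character(),
                   gene = character(), reads = double()), "e"
  )
  expect_equal(call_cells_threshold(empty), character(0))
})

test_that("swapping produces smaller sharing p-values than no swapping", {
  set.seed(90)
  p_at <- function(f, seed) {
    sim <- simulate_droplet(n_samples = 2, cells_per_sample = 100,
                            pool_size = 5000, genes = 30,
                            mean_molecules = 15, mean_reads = 8,
                            swap_fraction = f, seed = seed)
    sharing_test(sim$tables, pool_size = 5000)$p_value
  }
  seeds <- 1:20
  p_swap <- purrr::map_dbl(seeds, ~ p_at(0.05, .x))
  p_null <- purrr::map_dbl(seeds, ~ p_at(0, .x + 1000))
  expect_lt(median(p_swap), median(p_null))
  expect_gt(mean(p_null > p_swap), 0.7)
})
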