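test_that("available reads match brute-force enumeration of sharing donors", {
  design <- toy_design()
  counts <- uniform_counts(design, 10)
  # (R1,C3): donors are (R1,C1),(R1,C2),(R3,C3),(R4,C3)
  expect_equal(available_reads(counts, "R1", "C3"), 40)
  # brute force over every impossible combination
  exp_tab <- counts$counts[counts$counts$expected, ]
  dat <- impossible_regression_data(counts)
  for (i in seq_len(nrow(dat))) {
    donors <- mapply(function(r, c) {
      sum(r == dat$row[i], c == dat$col[i]) == 1
    }, exp_tab$row, exp_tab$col)
    expect_equal(dat$available[i], sum(exp_tab$library_size[donors]))
  }
  # zero-library designs give zero availability
  expect_equal(available_reads(uniform_counts(design, 0), "R1", "C3"), 0)
  # expected target is an argument error
  expect_error(available_reads(counts, "R1", "C1"), "expected combination")
})

test_that("exact linear impossible counts recover the per-destination rate", {
  design <- two_plate_design()  # 16 rows + 24 cols -> D = 38
  set.seed(42)
  sizes <- round(runif(192, 500, 5000))
  counts <- exact_linear_counts(design, sizes, rate = 0.001)
  est <- suppressWarnings(estimate_swap_impossible(counts))  # perfect fit
  expect_equal(est$diagnostics$destination_multiplier, 38)
  expect_equal(est$fraction, 0.038, tolerance = 1e-8)
  expect_lt(est$std_error, 1e-8)
  # all-zero impossible combinations -> fraction 0
  est0 <- estimate_swap_impossible(
    combination_counts(design, {
      exp_tab <- expected_combinations(design)
      tibble::tibble(row = exp_tab$row, col = exp_tab$col, library_size = sizes)
    })
  )
  expect_equal(est0$fraction, 0)
})

test_that("the impossible-combination estimate is invariant to relabelling and scaling", {
  design <- two_plate_design(3, 4)
  set.seed(7)
  sizes <- round(runif(24, 100, 1000))
  counts <- exact_linear_counts(design, sizes, rate = 0.002)
  est <- suppressWarnings(estimate_swap_impossible(counts))
  # relabel every barcode
  relab <- function(x) paste0("X", x)
  design2 <- plate_design(
    row_barcodes = lapply(design$row_barcodes, relab),
    col_barcodes = lapply(design$col_barcodes, relab)
  )
  ls2 <- dplyr::mutate(counts$counts, row = relab(row), col = relab(col))
  est2 <- suppressWarnings(estimate_swap_impossible(combination_counts(design2, ls2)))
  expect_equal(est2$fraction, est$fraction)
  # scale all library sizes by a constant
  ls3 <- dplyr::mutate(counts$counts, library_size = library_size * 10)
  est3 <- suppressWarnings(estimate_swap_impossible(combination_counts(design, ls3)))
  expect_equal(est3$fraction, est$fraction, tolerance = 1e-10)
})

test_that("the impossible-combination estimator recovers simulated swap rates", {
  design <- two_plate_design()
  sim <- simulate_plate(design, mean_reads = 5000, dispersion = 5,
                        swap_fraction = 0.02, seed = 101)
  est <- estimate_swap_impossible(sim$counts)
  expect_lt(abs(est$fraction - 0.02), 3 * est$std_error)
  # consistency: deeper sequencing tightens the estimate
  deep <- simulate_plate(design, mean_reads = 50000, dispersion = 5,
                         swap_fraction = 0.02, seed = 102)
  est_deep <- estimate_swap_impossible(deep$counts)
  expect_lt(abs(est_deep$fraction - 0.02), 3 * est_deep$std_error)
  expect_lt(est_deep$std_error, est$std_error)
})

test_that("an identical cross-platform pair yields zero swapped fraction", {
  pair <- simulate_crossplatform(n_rows = 4, n_cols = 6, genes = 50,
                                 swap_fraction = 0, seed = 3)
  expect_equal(pair$ref, pair$swapped)
  est <- estimate_swap_crossplatform(pair, n_boot = 0)
  expect_equal(est$fraction, 0, tolerance = 1e-10)
  expect_equal(unname(est$diagnostics$coefficients["self"]), 1,
               tolerance = 1e-8)
})

test_that("model-generated cross-platform data is recovered to numerical precision", {
  pair0 <- simulate_crossplatform(n_rows = 8, n_cols = 12, genes = 100,
                                  swap_fraction = 0, seed = 5)
  pred <- swapqc:::pair_predictors(pair0)
  X <- sum(pred$x); S <- sum(pred$s)
  swapped <- 0.98 * pred$x + 0.02 * (pred$s * X / S)
  pair <- cross_platform_pair(pair0$ref, swapped)
  est <- estimate_swap_crossplatform(pair, n_boot = 0)
  expect_equal(est$fraction, 0.02, tolerance = 1e-6)
})

test_that("the cross-platform estimator recovers a simulated swap fraction", {
  pair <- simulate_crossplatform(swap_fraction = 0.02, seed = 9)
  est <- estimate_swap_crossplatform(pair, n_boot = 50, seed = 10)
  expect_lt(abs(est$fraction - 0.02), 3 * est$std_error)
  expect_gt(est$std_error, 0)
})

test_that("gene-wise swap test is silent on identical platforms", {
  pair0 <- simulate_crossplatform(n_rows = 4, n_cols = 6, genes = 60,
                                  swap_fraction = 0, seed = 21)
  res <- genewise_swap_test(pair0, alpha = 0.5)
  expect_equal(res$n_sig_positive + res$n_sig_negative, 0)
})

test_that("gene-wise fits agree with stats::lm", {
  pair <- simulate_crossplatform(n_rows = 4, n_cols = 6, genes = 20,
                                 swap_fraction = 0.05, seed = 22)
  res <- tidy(genewise_swap_test(pair))
  pred <- swapqc:::pair_predictors(pair)
  for (g in sample.int(20, 5)) {
    fit <- lm(pair$swapped[g, ] ~ 0 + pred$x[g, ] + pred$s[g, ])
    sm <- summary(fit)$coefficients
    expect_equal(res$estimate_swap[g], sm[2, "Estimate"], tolerance = 1e-8)
    expect_equal(res$std_error[g], sm[2, "Std. Error"], tolerance = 1e-8)
    expect_equal(res$p_value[g], sm[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("gene-wise p-values are calibrated and uniform under the null", {
  # null: swapped = 1 * x + Gaussian noise, no swapping term; expression is
  # kept high so the non-negativity floor never truncates the noise
  set.seed(33)
  n_genes <- 1000
  grid <- tidyr::expand_grid(col = sprintf("C%02d", 1:12),
                             row = sprintf("R%02d", 1:8))
  lab <- paste(grid$row, grid$col, sep = ":")
  x <- matrix(stats::rnbinom(n_genes * 96, mu = 500, size = 5),
              nrow = n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)), lab))
  noise <- matrix(stats::rnorm(length(x), sd = 10), nrow = n_genes)
  swapped <- x + noise
  stopifnot(all(swapped >= 0))
  pair <- cross_platform_pair(x, swapped)
  res <- tidy(genewise_swap_test(pair))
  p <- res$p_value[res$tested]
  expect_gt(length(p), 900)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # type-I error at 5% within binomial 99% bounds
  reject <- mean(p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(reject - 0.05), bound)
})

test_that("a strong injected swapping term is detected in nearly all genes", {
  pair0 <- simulate_crossplatform(n_rows = 8, n_cols = 12, genes = 100,
                                  swap_fraction = 0, seed = 35)
  pred <- swapqc:::pair_predictors(pair0)
  mu <- 0.9 * pred$x + 0.05 * pred$s
  swapped <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                    dimnames = dimnames(mu))
  pair <- cross_platform_pair(pair0$ref, swapped)
  res <- genewise_swap_test(pair, alpha = 0.05)
  expect_gt(res$n_sig_positive / res$n_tested, 0.9)
  expect_equal(res$n_sig_negative, 0)
})

test_that("free-barcode association recovers an exact linear relationship", {
  ratios <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fractions <- 0.01 + 0.04 * ratios
  fit <- suppressWarnings(free_barcode_association(fractions, ratios))  # exact fit
  expect_equal(fit$slope, 0.04, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-10)
  expect_named(fit$band, c("ratio", "fit", "lwr", "upr"))
})

test_that("free-barcode association rejects degenerate inputs", {
  expect_error(free_barcode_association(c(0.01, 0.02), c(0.1, 0.2)), ">= 3")
  expect_error(free_barcode_association(rep(0.02, 4), rep(0.3, 4)), "constant")
})

test_that("free-barcode association is null-calibrated under permutation", {
  set.seed(55)
  ratios <- seq(0.1, 1, length.out = 8)
  fractions <- c(0.021, 0.019, 0.025, 0.018, 0.022, 0.020, 0.024, 0.023)
  p <- replicate(200, {
    free_barcode_association(sample(fractions), ratios)$p_value
  })
  # raw p approximately uniform: mean near 0.5, ~10% below 0.1
  expect_lt(abs(mean(p) - 0.5), 0.1)
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.08)
})
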