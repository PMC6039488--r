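#' Reads available for swapping into an impossible combination
#'
#' A single barcode swap can move a read into an impossible combination only
#' from an expected combination that shares exactly one barcode with it. The
#' "available" reads for an impossible target are therefore the summed library
#' sizes of those donor combinations.
#'
#' @param counts A [combination_counts()] object.
#' @param row,col The target combination's row and column barcode. Must be an
#'   impossible combination of the design.
#' @return The summed donor library size (a single non-negative number).
#' @export
available_reads <- function(counts, row, col) {
  stopifnot(inherits(counts, "combination_counts"))
  tab <- counts$counts
  hit <- tab$row == row & tab$col == col
  if (!any(hit)) stop("combination not in design: ", row, ":", col, call. = FALSE)
  if (tab$expected[hit]) {
    stop("(", row, ":", col, ") is an expected combination, not impossible",
         call. = FALSE)
  }
  exp_tab <- tab[tab$expected, ]
  donors <- shares_one_barcode(row, col, exp_tab$row, exp_tab$col)
  sum(exp_tab$library_size[donors])
}

#' Observed vs available reads for every impossible combination
#'
#' The regression table behind [estimate_swap_impossible()]: one line per
#' impossible combination with its observed library size and the reads
#' available to swap into it. Since an impossible pair (r, c) never matches an
#' expected combination on both barcodes, the available reads decompose into
#' per-row and per-column expected totals, which is how they are computed here.
#'
#' @param counts A [combination_counts()] object.
#' @return A tibble with columns `row`, `col`, `observed`, `available`.
#' @export
impossible_regression_data <- function(counts) {
  stopifnot(inherits(counts, "combination_counts"))
  tab <- counts$counts
  exp_tab <- tab[tab$expected, ]
  row_tot <- tapply(exp_tab$library_size, exp_tab$row, sum)
  col_tot <- tapply(exp_tab$library_size, exp_tab$col, sum)
  imp <- tab[!tab$expected, ]
  tibble::tibble(
    row = imp$row, col = imp$col,
    observed = imp$library_size,
    available = unname(row_tot[imp$row]) + unname(col_tot[imp$col])
  )
}

#' Estimate the swapped-read fraction from impossible combinations
#'
#' Regresses the library size of each impossible combination on the reads
#' available to swap into it (ordinary least squares, with an intercept to
#' absorb any constant contamination floor). The slope `m` is the fraction of
#' available reads that swap into *each* destination combination; a swapping
#' read has `D = (R - 1) + (C - 1)` possible single-swap destinations (R total
#' row barcodes, C total column barcodes), so the total swapped-read fraction
#' is `m * D`, with the slope's standard error scaled by the same multiplier.
#'
#' @param counts A [combination_counts()] object whose design has at least two
#'   plates (so impossible combinations exist).
#' @return A [swap_estimate()] with method `"impossible_regression"`;
#'   diagnostics record the slope, intercept, multiplier `D` and the number of
#'   impossible combinations fitted.
#' @export
estimate_swap_impossible <- function(counts) {
  dat <- impossible_regression_data(counts)
  if (nrow(dat) < 3) {
    stop("need at least 3 impossible combinations to fit; ",
         "does the design have two plates?", call. = FALSE)
  }
  if (stats::sd(dat$available) == 0) {
    stop("available reads are constant across impossible combinations; ",
         "slope unidentifiable", call. = FALSE)
  }
  fit <- lm(observed ~ available, data = dat)
  sm <- summary(fit)$coefficients
  m <- sm["available", "Estimate"]
  se_m <- sm["available", "Std. Error"]
  D <- (length(all_row_barcodes(counts$design)) - 1) +
       (length(all_col_barcodes(counts$design)) - 1)
  swap_estimate(
    fraction = min(max(m * D, 0), 1),
    std_error = se_m * D,
    method = "impossible_regression",
    diagnostics = list(
      slope = m, slope_se = se_m,
      intercept = unname(coef(fit)[1]),
      destination_multiplier = D,
      n_units = nrow(dat)
    )
  )
}

#' Paired counts of the same plate on two sequencing platforms
#'
#' Bundles gene x cell count matrices for the same plate of cells sequenced on
#' a low-swapping reference platform (non-patterned flow cell, HiSeq 2500
#' role) and on a patterned-flow-cell platform (HiSeq 4000 role). Cells are
#' identified by their barcode combination: column names must be
#' `"<row>:<col>"` labels, identical (as sets) in both matrices, as must the
#' gene rownames.
#'
#' @param counts_ref Gene x cell matrix from the reference platform.
#' @param counts_swapped Gene x cell matrix from the swapping-affected
#'   platform, same genes and cells.
#' @param design Optional [plate_design()]; if given, the cells must all be
#'   expected combinations of a single plate.
#' @return A `cross_platform_pair` object.
#' @export
cross_platform_pair <- function(counts_ref, counts_swapped, design = NULL) {
  counts_ref <- as.matrix(counts_ref)
  counts_swapped <- as.matrix(counts_swapped)
  if (is.null(rownames(counts_ref)) || is.null(colnames(counts_ref))) {
    stop("matrices need gene rownames and '<row>:<col>' colnames", call. = FALSE)
  }
  if (!setequal(rownames(counts_ref), rownames(counts_swapped)) ||
      !setequal(colnames(counts_ref), colnames(counts_swapped))) {
    stop("the two platforms must cover identical genes and cells", call. = FALSE)
  }
  counts_swapped <- counts_swapped[rownames(counts_ref), colnames(counts_ref),
                                   drop = FALSE]
  if (any(counts_ref < 0) || any(counts_swapped < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  parts <- strsplit(colnames(counts_ref), ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("colnames must be '<row>:<col>' combination labels", call. = FALSE)
  }
  rows <- purrr::map_chr(parts, 1)
  cols <- purrr::map_chr(parts, 2)
  if (!is.null(design)) {
    exp_tab <- expected_combinations(design)
    lab <- combo_label(exp_tab$row, exp_tab$col)
    bad <- setdiff(colnames(counts_ref), lab)
    if (length(bad)) {
      stop("cell(s) not expected combinations of the design: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
    plates <- unique(exp_tab$plate[match(colnames(counts_ref), lab)])
    if (length(plates) > 1) {
      stop("cells span more than one plate: ", paste(plates, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(ref = counts_ref, swapped = counts_swapped, rows = rows, cols = cols),
    class = "cross_platform_pair"
  )
}

# cells x cells logical matrices for barcode sharing within a pair
pair_sharing <- function(pair) {
  same_row <- outer(pair$rows, pair$rows, "==")
  same_col <- outer(pair$cols, pair$cols, "==")
  list(one = xor(same_row, same_col), none = !same_row & !same_col)
}

# the three gene x cell predictor matrices built from the reference counts
pair_predictors <- function(pair, ref = pair$ref) {
  sh <- pair_sharing(pair)
  list(
    x = ref,
    s = ref %*% (sh$one * 1),
    n = ref %*% (sh$none * 1)
  )
}

#' Estimate the swapped-read fraction from a cross-platform pair
#'
#' Models the swapping-affected expression of each cell as a non-negative
#' linear combination of three reference-platform predictors: the cell's own
#' profile `x_i`, the summed profiles `s_i` of cells sharing exactly one
#' barcode with it, and the summed profiles `n_i` of cells sharing no barcode.
#' The model `swapped = a x + b s + c n` is fitted once, pooled over all
#' (gene, cell) pairs, by non-negative least squares; the swapped fraction is
#' the relative contribution of other cells,
#' `(b S + c N) / (a X + b S + c N)`, with `X`, `S`, `N` the grand totals of
#' the predictors. Reference counts are first rescaled so both platforms have
#' equal grand totals, removing sequencing-depth differences from `a`.
#'
#' @param pair A [cross_platform_pair()].
#' @param n_boot Number of nonparametric bootstrap resamples over cells used
#'   for the standard error; `0` skips the bootstrap (`std_error` is `NA`).
#' @param seed Optional seed for the bootstrap, applied locally.
#' @return A [swap_estimate()] with method `"crossplatform_model"`;
#'   diagnostics record the coefficients and predictor totals.
#' @export
estimate_swap_crossplatform <- function(pair, n_boot = 100, seed = NULL) {
  stopifnot(inherits(pair, "cross_platform_pair"))
  tot_ref <- sum(pair$ref)
  if (tot_ref == 0) stop("reference matrix is all zero", call. = FALSE)
  sh <- pair_sharing(pair)
  if (!any(sh$one)) {
    stop("no cells share exactly one barcode; model unidentifiable", call. = FALSE)
  }
  ref <- pair$ref * (sum(pair$swapped) / tot_ref)
  pred <- pair_predictors(pair, ref)
  fit_fraction <- function(cells) {
    X <- cbind(as.vector(pred$x[, cells]), as.vector(pred$s[, cells]),
               as.vector(pred$n[, cells]))
    y <- as.vector(pair$swapped[, cells])
    beta <- pracma::lsqnonneg(X, y)$x
    tot <- beta * colSums(X)
    list(beta = beta, fraction = sum(tot[2:3]) / sum(tot))
  }
  all_cells <- seq_along(pair$rows)
  main <- fit_fraction(all_cells)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_local_seed(seed, {
      purrr::map_dbl(seq_len(n_boot), function(b) {
        fit_fraction(sample(all_cells, replace = TRUE))$fraction
      })
    })
    se <- stats::sd(boots)
  }
  swap_estimate(
    fraction = min(max(main$fraction, 0), 1),
    std_error = se,
    method = "crossplatform_model",
    diagnostics = list(
      coefficients = setNames(main$beta, c("self", "share_one", "share_none")),
      predictor_totals = setNames(
        c(sum(pred$x), sum(pred$s), sum(pred$n)), c("X", "S", "N")
      ),
      n_units = length(all_cells),
      n_boot = n_boot
    )
  )
}

#' Gene-wise test for a swapping contribution
#'
#' For each gene, fits the two-term model
#' `swapped(g, i) = a_g x_i(g) + b_g s_i(g)` across cells (no intercept; the
#' share-no-barcode term is second order and omitted) and tests `b_g = 0`
#' two-sidedly. P-values are Benjamini-Hochberg adjusted across tested genes.
#' Genes with all-zero reference counts, a degenerate design (collinear or
#' absent predictors) or fewer cells than parameters are reported untested.
#'
#' The per-gene fits are computed in closed form from the 2 x 2 normal
#' equations, vectorised across genes; this is exactly ordinary least squares.
#'
#' @param pair A [cross_platform_pair()].
#' @param alpha Significance level applied to the adjusted p-values when
#'   counting significantly positive / negative genes.
#' @return A `genewise_swap` object; `tidy()` returns the per-gene table,
#'   `glance()` the summary counts.
#' @export
genewise_swap_test <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "cross_platform_pair"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  pred <- pair_predictors(pair)
  x <- pred$x; s <- pred$s; y <- pair$swapped
  n <- ncol(x)
  df <- n - 2
  Sxx <- rowSums(x * x); Sss <- rowSums(s * s); Sxs <- rowSums(x * s)
  Sxy <- rowSums(x * y); Ssy <- rowSums(s * y); Syy <- rowSums(y * y)
  det <- Sxx * Sss - Sxs^2
  tested <- df >= 1 & Sxx > 0 & Sss > 0 &
    det > (.Machine$double.eps^0.5) * Sxx * Sss
  a_hat <- b_hat <- se <- tstat <- pval <- rep(NA_real_, nrow(x))
  a_hat[tested] <- (Sss * Sxy - Sxs * Ssy)[tested] / det[tested]
  b_hat[tested] <- (Sxx * Ssy - Sxs * Sxy)[tested] / det[tested]
  rss <- pmax(Syy - a_hat * Sxy - b_hat * Ssy, 0)
  sigma2 <- rss / df
  se[tested] <- sqrt(sigma2[tested] * Sxx[tested] / det[tested])
  ok <- tested & se > 0
  tstat[ok] <- b_hat[ok] / se[ok]
  pval[ok] <- 2 * pt(-abs(tstat[ok]), df)
  pval[tested & !ok] <- 1  # perfect fit: no evidence against b = 0
  adj <- rep(NA_real_, nrow(x))
  adj[tested] <- p.adjust(pval[tested], method = "BH")
  genes <- tibble::tibble(
    gene = rownames(x),
    estimate_self = a_hat, estimate_swap = b_hat,
    std_error = se, statistic = tstat,
    p_value = pval, adj_p_value = adj, tested = tested
  )
  structure(
    list(
      genes = genes, alpha = alpha,
      n_tested = sum(tested),
      n_sig_positive = sum(tested & adj < alpha & b_hat > 0, na.rm = TRUE),
      n_sig_negative = sum(tested & adj < alpha & b_hat < 0, na.rm = TRUE)
    ),
    class = "genewise_swap"
  )
}

#' @export
print.genewise_swap <- function(x, ...) {
  cat("<genewise_swap> ", x$n_tested, " genes tested; at adjusted p < ",
      x$alpha, ": ", x$n_sig_positive, " positive, ", x$n_sig_negative,
      " negative swapping terms\n", sep = "")
  invisible(x)
}

#' @rdname genewise_swap_test
#' @param x A `genewise_swap` object.
#' @param ... Unused.
#' @method tidy genewise_swap
#' @export
tidy.genewise_swap <- function(x, ...) x$genes

#' @rdname genewise_swap_test
#' @method glance genewise_swap
#' @export
glance.genewise_swap <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes), n_tested = x$n_tested,
    n_sig_positive = x$n_sig_positive, n_sig_negative = x$n_sig_negative,
    alpha = x$alpha
  )
}

#' Association of per-plate swap fractions with free-barcode concentration
#'
#' Ordinary least-squares regression (with intercept) of per-plate
#' swapped-read fraction estimates on the per-plate ratio of free-barcode to
#' cDNA concentration, with a two-sided t-test of the slope. Used to ask
#' whether leftover free barcode drives swapping.
#'
#' @param swap_fractions Numeric vector of per-plate swapped fractions.
#' @param ratios Numeric vector of per-plate free-barcode/cDNA ratios, same
#'   length, at least 3 plates, non-constant.
#' @return A `barcode_association` object with elements `slope`, `std_error`,
#'   `p_value`, `intercept`, `n`, the input `data`, and `band` (a tibble of
#'   fitted values with a 95% confidence band over the ratio range, for
#'   plotting). `tidy()` returns the coefficient table.
#' @export
free_barcode_association <- function(swap_fractions, ratios) {
  stopifnot(is.numeric(swap_fractions), is.numeric(ratios))
  if (length(swap_fractions) != length(ratios) || length(ratios) < 3) {
    stop("need >= 3 plates with one fraction and one ratio each", call. = FALSE)
  }
  if (stats::sd(ratios) == 0) {
    stop("ratios are constant; slope unidentifiable", call. = FALSE)
  }
  dat <- tibble::tibble(ratio = ratios, fraction = swap_fractions)
  fit <- lm(fraction ~ ratio, data = dat)
  sm <- summary(fit)$coefficients
  grid <- tibble::tibble(ratio = seq(min(ratios), max(ratios), length.out = 50))
  ci <- stats::predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  structure(
    list(
      slope = sm["ratio", "Estimate"],
      std_error = sm["ratio", "Std. Error"],
      p_value = sm["ratio", "Pr(>|t|)"],
      intercept = unname(coef(fit)[1]),
      n = length(ratios),
      data = dat,
      band = dplyr::bind_cols(grid, tibble::as_tibble(ci))
    ),
    class = "barcode_association"
  )
}

#' @export
print.barcode_association <- function(x, ...) {
  cat("<barcode_association> slope ", signif(x$slope, 3), " ± ",
      signif(x$std_error, 3), " (p = ", signif(x$p_value, 3), ", n = ", x$n,
      " plates)\n", sep = "")
  invisible(x)
}

#' @rdname free_barcode_association
#' @param x A `barcode_association` object.
#' @param ... Unused.
#' @method tidy barcode_association
#' @export
tidy.barcode_association <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "ratio"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$std_error),
    p.value = c(NA_real_, x$p_value)
  )
}
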