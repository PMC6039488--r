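#' Plot the impossible-combination swap regression
#'
#' Scatter of observed reads in each impossible combination against the reads
#' available to swap into it, with the ordinary least-squares fit whose slope
#' drives [estimate_swap_impossible()].
#'
#' @param counts A [combination_counts()] object.
#' @return A ggplot.
#' @export
plot_impossible_regression <- function(counts) {
  dat <- impossible_regression_data(counts)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$available, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(
      x = "Available swapping reads (expected combinations sharing one barcode)",
      y = "Observed swapped reads (impossible combination library size)"
    ) +
    ggplot2::theme_bw()
}

#' @describeIn sharing_test Tile plot of pairwise sharing, shaded by
#'   `-log10` adjusted p-value and annotated with the overlap counts.
#' @param object A `sharing_result`.
#' @param ... Unused.
#' @method autoplot sharing_result
#' @export
autoplot.sharing_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$neglog_p <- -log10(pmax(dat$adjusted_p, 1e-300))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                    fill = .data$neglog_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$overlap), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "-log10 adj. p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cell-barcode sharing between samples") +
    ggplot2::theme_minimal()
}

#' @describeIn free_barcode_association Scatter of per-plate swap fractions
#'   against free-barcode/cDNA ratio with the fitted line and 95% confidence
#'   band.
#' @param object A `barcode_association`.
#' @method autoplot barcode_association
#' @export
autoplot.barcode_association <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ratio, y = .data$fraction)) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$ratio, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$ratio, y = .data$fit),
      inherit.aes = FALSE, colour = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Free barcode / cDNA concentration ratio",
                  y = "Estimated swapped-read fraction") +
    ggplot2::theme_bw()
}

#' @describeIn remove_swapped_molecules Stacked bar chart of retained /
#'   removed molecules per sample.
#' @param object A `cleaning_report`.
#' @param ... Unused.
#' @method autoplot cleaning_report
#' @export
autoplot.cleaning_report <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      c("retained", "removed_swapped", "removed_unresolved"),
      names_to = "status", values_to = "molecules"
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample, y = .data$molecules,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Molecules",
                  title = "Swapped-molecule cleaning per sample") +
    ggplot2::theme_minimal()
}
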