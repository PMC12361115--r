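#' Plot a gap-threshold scan
#'
#' Complete and Partial counts against the maximum allowed intergenic
#' distance, with an optional vertical line at the detected plateau.
#'
#' @param scan Output of [scan_gap_thresholds()].
#' @param plateau Optional plateau threshold (bp) to mark.
#' @return A ggplot object.
#' @export
plot_gap_scan <- function(scan, plateau = NULL) {
  long <- tidyr::pivot_longer(scan, c("n_complete", "n_partial"),
                              names_to = "type", values_to = "n") |>
    mutate(type = ifelse(.data$type == "n_complete", "Complete",
                         "Partial"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$max_gap, y = .data$n,
                                          colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "maximum intergenic distance (bp)",
                  y = "units with cluster type", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(plateau)) {
    p <- p + ggplot2::geom_vline(xintercept = plateau,
                                 linetype = "dashed")
  }
  p
}

#' @describeIn estimate_kde Density of log10 e-values with modes (solid)
#'   and antimodes (dashed) marked; an optional `cutoff` (e-value) is
#'   drawn as a dotted line.
#' @param object A `nuoscan_kde`.
#' @param cutoff Optional e-value cutoff to mark.
#' @param ... Unused.
#' @method autoplot nuoscan_kde
#' @export
autoplot.nuoscan_kde <- function(object, cutoff = NULL, ...) {
  df <- tibble(log10_evalue = object$grid, density = object$density)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_evalue,
                                        y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$grid[object$modes],
                        colour = "steelblue") +
    ggplot2::labs(x = "log10(e-value)", y = "density") +
    ggplot2::theme_minimal()
  if (length(object$antimodes) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$grid[object$antimodes],
      linetype = "dashed", colour = "grey40")
  }
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = log10(max(cutoff, 1e-300)),
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}

#' @describeIn chi_square_independence Pearson-residual heatmap
#'   (lifestyle by variant); positive cells mark association, negative
#'   dissociation.
#' @param object A `contingency_result`.
#' @method autoplot contingency_result
#' @export
autoplot.contingency_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$variant, y = .data$lifestyle,
                                   fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$residual)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson\nresidual") +
    ggplot2::theme_minimal()
}

#' Plot the variant distribution by taxon
#'
#' Stacked percentage bars of species per variant within each taxon, as
#' produced by [summarize_by_rank()].
#'
#' @param rank_distribution Output of [summarize_by_rank()].
#' @return A ggplot object.
#' @export
plot_variant_distribution <- function(rank_distribution) {
  df <- mutate(rank_distribution,
               variant = factor(.data$variant,
                                levels = variant_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$pct,
                                   fill = .data$variant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of species", fill = "variant") +
    ggplot2::theme_minimal()
}
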