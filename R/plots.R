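# ggplot2 graphics for the main result types.

#' Plot an association scan
#'
#' @param object a `chill_assoc` tibble.
#' @param type `"qq"` (expected vs observed -log10 p with the identity
#'   line) or `"manhattan"` (per-position -log10 p with the candidate
#'   threshold).
#' @param threshold_nlp horizontal cutoff drawn on the Manhattan panel.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.chill_assoc <- function(object, type = c("qq", "manhattan"),
                                 threshold_nlp = 4.5, ...) {
  type <- match.arg(type)
  if (type == "qq") {
    qq <- qq_table(object$p)
    ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::labs(
        x = expression(Expected ~ -log[10](p)),
        y = expression(Observed ~ -log[10](p)),
        title = sprintf("%s scan QQ plot (lambda[GC] = %.3f)",
                        attr(object, "model"), attr(object, "lambda_gc"))) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    if (!all(c("chrom", "pos") %in% names(df))) {
      abort("Manhattan plot needs `chrom` and `pos` columns.")
    }
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p,
                                     colour = .data$chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::geom_hline(yintercept = threshold_nlp, linetype = 2,
                          colour = "red") +
      ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                          space = "free_x") +
      ggplot2::labs(x = "Position (bp)", y = expression(-log[10](p))) +
      ggplot2::theme_minimal()
  }
}

#' Heat-map of per-cell rosette areas on the tray grid
#'
#' @param measurements tibble from [process_tray()].
#' @return a ggplot object.
#' @export
plot_tray_areas <- function(measurements) {
  ggplot2::ggplot(measurements,
                  ggplot2::aes(x = .data$cell_col, y = .data$cell_row,
                               fill = .data$area_px)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Area (px)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row") +
    ggplot2::theme_minimal()
}

#' Histogram of proportionate tolerance across a panel
#'
#' @param tolerance numeric vector from [proportionate_tolerance()].
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_tolerance_distribution <- function(tolerance, bins = 40) {
  ggplot2::ggplot(tibble(tolerance = tolerance),
                  ggplot2::aes(x = .data$tolerance)) +
    ggplot2::geom_histogram(bins = bins, fill = "seagreen", colour = "white") +
    ggplot2::labs(x = "Proportionate tolerance (%)", y = "Ecotypes") +
    ggplot2::theme_minimal()
}
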