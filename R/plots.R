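# ggplot2 views of the standard result types: the expression-response
# scatter with fitted lines, the intercept bar plot with stars, and a
# raster view of a synthetic cell.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Spearman versus expression, with extrapolation lines
#'
#' The per-cell scatter of mean Spearman coefficient against bait (or
#' prey) expression, one colour per condition, with each condition's
#' least-squares line extended to zero expression — the plot from which
#' the zero-expression intercepts are read.
#'
#' @param object A [fit_zero_expression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bench_extrapolation <- function(object, ...) {
  pts <- attr(object, "measurements")
  xcol <- paste0(attr(object, "axis"), "_expression")
  fits <- tibble::as_tibble(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data[[xcol]], y = .data$rho_mean,
                                    colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$condition)) +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(x = paste(attr(object, "axis"), "expression (a.u.)"),
                  y = "mean Spearman coefficient",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Bar plot of zero-expression intercepts
#'
#' One bar per condition showing the extrapolated Spearman coefficient at
#' zero bait expression, with an error bar of one intercept standard error
#' and, when comparisons are present, significance stars above each bar.
#'
#' @param report A [condition_report()] tibble.
#' @return A ggplot object.
#' @export
plot_condition_report <- function(report) {
  stopifnot(is.data.frame(report),
            all(c("condition", "intercept", "intercept_sd") %in% names(report)))
  p <- ggplot2::ggplot(report,
                       ggplot2::aes(x = .data$condition, y = .data$intercept)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$intercept - .data$intercept_sd,
                   ymax = .data$intercept + .data$intercept_sd),
      width = 0.15) +
    ggplot2::labs(x = NULL,
                  y = "Spearman coefficient at zero bait expression") +
    ggplot2::theme_minimal()
  if ("stars" %in% names(report)) {
    lab <- dplyr::mutate(report,
                         y = .data$intercept +
                           dplyr::coalesce(.data$intercept_sd, 0) + 0.02,
                         stars = dplyr::coalesce(.data$stars, ""))
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(y = .data$y,
                                             label = .data$stars),
                                size = 6)
  }
  p
}

#' Raster view of a synthetic cell
#'
#' Bait and prey channels side by side on a common intensity scale.
#'
#' @param object A `synthetic_cell`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_cell <- function(object, ...) {
  to_df <- function(m, channel) {
    tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   intensity = as.vector(m), channel = channel)
  }
  df <- dplyr::bind_rows(to_df(object$bait, "bait"),
                         to_df(object$prey, "prey"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$cell_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
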