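# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a master-curve fit
#'
#' @param x A `master_fit`.
#' @param ... Unused.
#' @return One row per 5PL parameter: `term`, `estimate`.
#' @export
tidy.master_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "D", "C", "B", "G"),
                 estimate = unlist(x$params[c("A", "D", "C", "B", "G")]))
}

#' @rdname tidy.master_fit
#' @return `glance()`: one-row fit summary (points, outliers, RSS on
#'   kept points, refinement rounds, convergence).
#' @export
glance.master_fit <- function(x, ...) {
  kept <- !x$outlier
  tibble::tibble(n_points = length(x$residuals),
                 n_outliers = sum(x$outlier),
                 rss_kept = sum(x$residuals[kept]^2),
                 sigma = stats::sd(x$residuals[kept]),
                 n_refinement_rounds = x$n_refinement_rounds,
                 converged = x$converged)
}

#' Tidy a slide quantification
#'
#' @param x An `rppm_quant`.
#' @param ... Unused.
#' @return The per-sample quantification tibble (`sample_id`,
#'   `block_id`, `linear_slope`, `y_intercept`, `n_points_used`,
#'   `usable`).
#' @export
tidy.rppm_quant <- function(x, ...) x$quant

#' @rdname tidy.rppm_quant
#' @export
glance.rppm_quant <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_samples = nrow(x$quant),
                   n_blocks = length(x$blocks),
                   n_spots_excluded = x$n_excluded),
    glance(x$master))
}

#' Tidy an ANOVA table
#'
#' @param x An `anova_table`.
#' @param ... Unused.
#' @return The underlying tibble (`effect`, `ss`, `df`, `statistic`,
#'   `p.value`).
#' @export
tidy.anova_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Diagnostic plot of a master-curve fit
#'
#' All pooled points in log-log space, outliers highlighted, with the
#' fitted 5PL overlaid.
#'
#' @param object A `master_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.master_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, outlier = object$outlier)
  xs <- seq(min(df$x) - 1, max(df$x) + 1, length.out = 200)
  curve <- tibble::tibble(x = xs, y = eval_5pl(xs, object$params))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "black") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log2 relative concentration",
                  y = "log10 net intensity",
                  colour = "outlier",
                  title = "RPPM master curve") +
    ggplot2::theme_minimal()
}

#' Per-sample y-intercept plot for a quantified slide
#'
#' @param object An `rppm_quant`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rppm_quant <- function(object, ...) {
  ggplot2::ggplot(object$quant,
                  ggplot2::aes(x = stats::reorder(.data$sample_id,
                                                  .data$y_intercept),
                               y = .data$y_intercept,
                               fill = .data$block_id)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "y-intercept (log10 AU at step 0)",
                  title = "RPPM protein readout") +
    ggplot2::theme_minimal()
}

#' Axial slice heatmap of a scalar volume
#'
#' @param object A `scalar_volume`.
#' @param slice 0-based z index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_volume <- function(object, slice = NULL, ...) {
  shp <- dim(object$data)
  if (is.null(slice)) slice <- shp[3] %/% 2
  sl <- object$data[, , slice + 1]
  df <- tidyr::expand_grid(i = seq_len(shp[1]) - 1, j = seq_len(shp[2]) - 1)
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(object$kind, " (z = ", slice, ")"),
                  x = "i", y = "j") +
    ggplot2::theme_minimal()
}

#' Mean +/- SEM group plot
#'
#' @param summary A tibble from [summarize_mean_sem()] with grouping
#'   columns `injury` and `day`.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$day, y = .data$mean,
                               group = .data$injury,
                               colour = .data$injury)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(y = "mean ± SEM") +
    ggplot2::theme_minimal()
}
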