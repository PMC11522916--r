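#' Plot benthic composition per year
#'
#' Stacked composition bars of the pooled per-year cover table.
#'
#' @param cover Wide cover tibble from [compute_cover()] with `by = "year"`.
#' @return A ggplot object.
#' @export
plot_cover_composition <- function(cover) {
  long <- tidyr::pivot_longer(cover,
                              dplyr::any_of(c(benthic_categories(), "unclassified")),
                              names_to = "category", values_to = "cover")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$year), y = .data$cover,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "survey year", y = "cover (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot rarefaction/extrapolation curves
#'
#' @param diversity Long tibble from [rarefaction_curve()] (optionally with a
#'   `unit` column from the pipeline).
#' @return A ggplot object faceted by Hill order.
#' @export
plot_rarefaction <- function(diversity) {
  grp <- if ("unit" %in% names(diversity)) "unit" else NULL
  p <- ggplot2::ggplot(diversity,
                       ggplot2::aes(x = .data$m, y = .data$estimate,
                                    linetype = .data$method)) +
    ggplot2::facet_wrap(~q, scales = "free_y",
                        labeller = ggplot2::label_both)
  if (!is.null(grp)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$unit,
                                             group = paste(.data$unit, .data$method)))
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$method))
  }
  p + ggplot2::labs(x = "sample size", y = "Hill diversity") +
    ggplot2::theme_minimal()
}

#' Plot per-year functional trait metrics
#'
#' @param metrics Tibble from [functional_metrics()].
#' @return A ggplot object with one panel per metric.
#' @export
plot_functional_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics, c("n_taxa", "volume_fraction", "redundancy_5nn", "dispersion"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$year), y = .data$value,
                                     group = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "survey year", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn pcoa Autoplot method: unit scores on the first two axes.
#' @param object A `reef_pcoa` object.
#' @param ... Unused.
#' @export
autoplot.reef_pcoa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PCoA1, y = .data$PCoA2,
                                   label = .data$unit)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PCoA1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PCoA2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn kde_occupancy Autoplot method: density heat map with the
#'   50% and 95% occupancy contours and the taxon positions.
#' @param object A `reef_kde` object.
#' @param ... Unused.
#' @export
autoplot.reef_kde <- function(object, ...) {
  grid <- tidyr::expand_grid(x = object$x, y = object$y)
  grid$z <- as.numeric(t(object$z))
  pts <- tibble::tibble(x = object$points[, 1], y = object$points[, 2])
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z),
                          breaks = object$levels, colour = "white") +
    ggplot2::geom_point(data = pts, colour = "black", size = 0.8) +
    ggplot2::labs(x = sprintf("PCoA%d", object$axes[1]),
                  y = sprintf("PCoA%d", object$axes[2]), fill = "density") +
    ggplot2::theme_minimal()
}

#' @describeIn dbrda_forward_select Autoplot method: site scores with
#'   predictor arrows.
#' @param object A `reef_dbrda` object.
#' @param ... Unused.
#' @export
autoplot.reef_dbrda <- function(object, ...) {
  if (is.null(object$site_scores)) {
    rs_abort("null db-RDA model (no predictors selected); nothing to plot")
  }
  sites <- tibble::as_tibble(object$site_scores, rownames = "unit")
  n_ax <- ncol(object$site_scores)
  ax2 <- if (n_ax >= 2) "dbRDA2" else "dbRDA1"
  arrows <- tibble::as_tibble(object$predictor_scores, rownames = "predictor")
  scale_f <- max(abs(sites$dbRDA1))
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$dbRDA1, y = .data[[ax2]])) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = 0, y = 0, xend = .data$dbRDA1 * scale_f,
                   yend = .data[[ax2]] * scale_f),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = arrows,
                       ggplot2::aes(x = .data$dbRDA1 * scale_f,
                                    y = .data[[ax2]] * scale_f,
                                    label = .data$predictor),
                       vjust = -0.5, size = 3) +
    ggplot2::theme_minimal()
}
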