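#' Tidy a voxel-wise fit result
#'
#' One row per masked voxel with the parameter estimates, joined with the
#' convergence diagnostics.
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @returns A tibble.
#' @exportS3Method generics::tidy
tidy.fit_result <- function(x, ...) {
  dplyr::left_join(x$estimates,
                   dplyr::select(x$diagnostics, "voxel", "residual_norm",
                                 "converged", "n_restarts"),
                   by = "voxel")
}

#' @rdname tidy.fit_result
#' @exportS3Method generics::glance
glance.fit_result <- function(x, ...) {
  tibble::tibble(model = x$model, n_voxels = nrow(x$estimates),
                 n_failed = sum(!x$diagnostics$converged),
                 median_residual = median(x$diagnostics$residual_norm,
                                          na.rm = TRUE))
}

#' @rdname tidy.fit_result
#' @exportS3Method generics::tidy
tidy.vertex_stat_map <- function(x, ...) {
  dplyr::mutate(x$stats, valid = x$valid, metric = x$metric)
}

#' @rdname tidy.fit_result
#' @exportS3Method generics::glance
glance.vertex_stat_map <- function(x, ...) {
  tibble::tibble(metric = x$metric, n_valid = sum(x$valid),
                 n_vertices = length(x$valid),
                 mean_abs_t = mean(abs(x$stats$t[x$valid])),
                 df = median(x$stats$df, na.rm = TRUE))
}

#' @rdname tidy.fit_result
#' @exportS3Method generics::tidy
tidy.spin_test_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm,
                 null_mean = mean(attr(x, "null")),
                 null_sd = sd(attr(x, "null")))
}

#' Plot a vertex statistic map on the unfolded grid
#'
#' Tile map of a per-vertex statistic in unfolded (AP x PD) coordinates, the
#' standard flat-map view of hippocampal surface data.
#'
#' @param object A `vertex_stat_map`.
#' @param surface The surface the map lives on.
#' @param ... Unused.
#' @returns A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vertex_stat_map <- function(object, surface, ...) {
  d <- dplyr::bind_cols(surface$vertices[, c("ap", "pd")],
                        t = object$stats$t)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ap, y = .data$pd,
                                  fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "anterior-posterior", y = "proximal-distal",
                  fill = "t (age)",
                  title = paste0("Age-contrast map: ", object$metric)) +
    ggplot2::coord_fixed(ratio = 0.5) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vertex_stat_map
#' @exportS3Method ggplot2::autoplot
autoplot.spin_test_result <- function(object, ...) {
  nd <- tibble::tibble(r = attr(object, "null"))
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$r, colour = "#B2182B",
                        linewidth = 1) +
    ggplot2::labs(x = "null Pearson R (spun maps)", y = "count",
                  title = sprintf("Spin test: R = %.3f, p = %.4f",
                                  object$r, object$p)) +
    ggplot2::theme_minimal()
}

#' Age-correlation scatter panels
#'
#' The standard parcel-level view: metric value against age per parcel with
#' the least-squares line and the Pearson R annotation.
#'
#' @param table Long metric table (hemisphere-averaged).
#' @param metric Which metric to plot.
#' @param correlations Optional [age_correlation_all()] results for
#'   annotations.
#' @returns A ggplot, faceted by parcel.
#' @export
plot_age_scatter <- function(table, metric, correlations = NULL) {
  d <- dplyr::filter(table, .data$metric == !!metric)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#B2182B", linewidth = 0.7) +
    ggplot2::facet_wrap(~parcel, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = metric) +
    ggplot2::theme_minimal()
  if (!is.null(correlations)) {
    ann <- correlations |>
      dplyr::filter(.data$metric == !!metric) |>
      dplyr::mutate(label = sprintf("R = %.2f%s", .data$r, .data$asterisk))
    p <- p + ggplot2::geom_text(data = ann,
                                ggplot2::aes(label = .data$label),
                                x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                                inherit.aes = FALSE, size = 3)
  }
  p
}

#' Reference-battery correlation heatmap
#'
#' Heatmaps of the Pearson R (and spin-test p) between age-contrast maps and
#' reference maps.
#'
#' @param battery A [reference_map_battery()] tibble.
#' @param what `"r"` or `"p"`.
#' @returns A ggplot.
#' @export
plot_reference_battery <- function(battery, what = c("r", "p")) {
  what <- match.arg(what)
  ggplot2::ggplot(battery,
                  ggplot2::aes(x = .data$reference, y = .data$metric,
                               fill = .data[[what]])) +
    ggplot2::geom_tile() +
    (if (what == "r")
      ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B", midpoint = 0,
                                    limits = c(-1, 1))
     else ggplot2::scale_fill_gradient(low = "#B2182B", high = "white",
                                       limits = c(0, 1))) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf(if (what == "r") "%.2f" else "%.3f", .data[[what]])),
      size = 2.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = what) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
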