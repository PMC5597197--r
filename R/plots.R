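#' Trace plot of posterior draws
#'
#' @param object An `lf_draws` object.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lf_draws <- function(object, parameters = NULL, ...) {
  df <- tibble::as_tibble(object$draws, .name_repair = "minimal")
  if (is.null(colnames(object$draws)))
    names(df) <- paste0("theta", seq_along(df))
  df$.draw <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -".draw", names_to = "term",
                              values_to = "value")
  if (!is.null(parameters))
    long <- dplyr::filter(long, .data$term %in% parameters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL)
}

#' Raster plot of a canopy height model
#'
#' @param object An `lf_grid` (e.g. from [build_chm()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lf_grid <- function(object, ...) {
  nx <- nrow(object$values); ny <- ncol(object$values)
  df <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  df$x <- object$origin[1] + (df$ix - 0.5) * object$res
  df$y <- object$origin[2] + (df$iy - 0.5) * object$res
  df$height <- object$values[cbind(df$ix, df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "height (m)")
}

#' Leaf area density profile plot
#'
#' @param profile Output of [lad_profile()].
#' @return A ggplot (LAD against layer midpoint height).
#' @export
plot_lad_profile <- function(profile) {
  df <- dplyr::mutate(profile, z_mid = (.data$z_bottom + .data$z_top) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lad, y = .data$z_mid)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(LAD ~ (m^2 / m^3)), y = "height (m)")
}

#' DIC-difference distributions per ALS variable
#'
#' Box plots of the DIC difference across runs, grouped by ALS variable
#' (lower values mean the structure variable improves the model).
#'
#' @param run_summary The `summary` tibble from [run_all()] (or any tibble
#'   with `indicator` and `delta_dic`).
#' @return A ggplot.
#' @export
plot_delta_dic <- function(run_summary) {
  df <- dplyr::filter(run_summary, is.finite(.data$delta_dic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indicator, y = .data$delta_dic)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(Delta * DIC)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Non-negligible effect counts per extraction radius
#'
#' @param by_radius The `by_radius` tibble from [count_tables()].
#' @return A ggplot bar chart.
#' @export
plot_effect_counts <- function(by_radius) {
  ggplot2::ggplot(by_radius,
                  ggplot2::aes(x = factor(.data$radius),
                               y = .data$n_non_negligible,
                               fill = .data$site)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "extraction radius", y = "non-negligible effects",
                  fill = NULL)
}
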