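# ggplot2 autoplot methods for the result types

#' @export
autoplot.ld_decay <- function(object, ...) {
  df <- dplyr::filter(object, .data$n_pairs > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_start_kb + .data$bin_end_kb) / 2, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @param object A `grm_pca` result.
#' @param group Optional named vector animal -> group for colouring.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @rdname grm_pca
#' @export
autoplot.grm_pca <- function(object, group = NULL, components = c(1, 2), ...) {
  sc <- tidy(object, n_components = max(components)) |>
    dplyr::filter(.data$component %in% components) |>
    dplyr::mutate(component = paste0("PC", .data$component)) |>
    tidyr::pivot_wider(id_cols = "animal", names_from = "component",
                       values_from = "score")
  labs <- sprintf("PC%d (%.2f%%)", components,
                  object$pct_variance[components])
  p <- ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[paste0("PC", components[1])]],
    y = .data[[paste0("PC", components[2])]]))
  if (!is.null(group)) {
    sc$group <- group[sc$animal]
    p <- ggplot2::ggplot(sc, ggplot2::aes(
      x = .data[[paste0("PC", components[1])]],
      y = .data[[paste0("PC", components[2])]], colour = .data$group))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = labs[1], y = labs[2], title = "G-matrix PCA") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gibbs_fit <- function(object, parameters = NULL, ...) {
  df <- as_tibble(object$vc_chain) |>
    dplyr::mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-"sample", names_to = "parameter",
                        values_to = "value")
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = NULL,
                  title = "Variance-component traces") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.validation_report <- function(object, metric = "R", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$scenario_size, y = .data[[metric]],
    colour = .data$population)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "joint reference size", y = metric,
                  title = "Joint-reference validation") +
    ggplot2::theme_minimal()
}
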