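#' Plot helpers for experiment grids and SIR trajectories
#'
#' `autoplot.pbsi_grid()` (and the `plot_fss_curve()` / `plot_ls_curve()`
#' wrappers) draw the standard diagnostic figures: mean final spreading
#' scope against the spreading rate or the seed-set size, one line per
#' method/variant, and seed scatter (LS) against the seed-set size.
#'
#' @param object A `pbsi_grid` tibble from [run_grid()].
#' @param x Which variable to put on the x axis: `"beta"` or `"rho"`.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @method autoplot pbsi_grid
#' @export
autoplot.pbsi_grid <- function(object, x = c("beta", "rho"), ...) {
  x <- match.arg(x)
  df <- dplyr::mutate(object,
                      series = paste(.data$method, .data$variant, sep = "/"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$fss_mean,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fss_mean - .data$fss_se,
                                        ymax = .data$fss_mean + .data$fss_se),
                           width = 0) +
    ggplot2::labs(x = x, y = "mean final spreading scope",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbsi_grid
#' @param grid A `pbsi_grid` tibble.
#' @export
plot_fss_curve <- function(grid, x = c("beta", "rho")) {
  autoplot.pbsi_grid(grid, x = match.arg(x))
}

#' @rdname autoplot.pbsi_grid
#' @export
plot_ls_curve <- function(grid) {
  df <- grid |>
    dplyr::distinct(.data$method, .data$variant, .data$rho, .data$ls) |>
    dplyr::mutate(series = paste(.data$method, .data$variant, sep = "/"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$ls,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of spreaders",
                  y = "mean distance between spreaders (LS)",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbsi_grid
#' @param result An `sir_result` from [sir_run()].
#' @export
plot_trajectory <- function(result) {
  df <- tidyr::pivot_longer(tidy(result), c("n_s", "n_i", "n_r"),
                            names_to = "compartment", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$count,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "nodes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
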