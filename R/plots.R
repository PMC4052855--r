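## ggplot2 renderings of trajectories and patterns.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ionization trajectory
#'
#' @param object An `fx_ionization_traj`.
#' @param ... Unused.
#' @return A ggplot: average ionization and bound fraction versus time.
#' @method autoplot fx_ionization_traj
#' @export
autoplot.fx_ionization_traj <- function(object, ...) {
  df <- tibble::tibble(
    t_fs = rep(object$t_fs, 2),
    value = c(object$z, object$w),
    quantity = rep(c("ionization z (e/atom)", "bound fraction w"),
                   each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_fs, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "time (fs)", y = NULL,
      title = sprintf("Average ionization at %.3g GGy/fs",
                      attr(object, "dose_rate_gy_fs") / 1e9)
    )
}

#' Plot a displacement trajectory
#'
#' @param object An `fx_displacement_traj`.
#' @param ... Unused.
#' @return A ggplot of the RMS displacement versus time.
#' @method autoplot fx_displacement_traj
#' @export
autoplot.fx_displacement_traj <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_fs, .data$sigma_angstrom)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (fs)", y = "per-axis RMS displacement (Å)",
      title = sprintf("Displacement at %.3g GGy/fs",
                      attr(object, "dose_rate_gy_fs") / 1e9)
    )
}

#' Plot a diffraction pattern
#'
#' Line grids plot intensity versus |q| on a log scale; planar grids render a
#' max-normalized raster.
#'
#' @param object An `fx_pattern`.
#' @param column Which column to show (`"intensity"`, `"bragg"`, `"diffuse"`
#'   or `"realized"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fx_pattern
#' @export
autoplot.fx_pattern <- function(object, column = "intensity", ...) {
  planar <- length(unique(object$qy)) > 1 && length(unique(object$qx)) > 1
  if (planar) {
    df <- tibble::tibble(qx = object$qx, qy = object$qy,
                         value = object[[column]] / max(object[[column]]))
    ggplot2::ggplot(df, ggplot2::aes(.data$qx, .data$qy,
                                     fill = log10(.data$value + 1e-9))) +
      ggplot2::geom_raster() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "qx (1/Å)", y = "qy (1/Å)",
                    fill = "log10 I/Imax")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$q, .data[[column]])) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "q (1/Å)", y = sprintf("%s (photons/node)", column))
  }
}

#' @importFrom rlang .data
NULL
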