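#' Plot a trajectory
#'
#' Time series of all state components (`type = "time"`), or the phase
#' projection onto two chosen components (`type = "phase"`).
#'
#' @param object An `fhn_trajectory`.
#' @param type `"time"` or `"phase"`.
#' @param vars For `type = "phase"`, the two components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fhn_trajectory <- function(object, type = c("time", "phase"),
                                    vars = c("u", "v"), ...) {
  type <- match.arg(type)
  if (type == "time") {
    long <- tidyr::pivot_longer(as_tibble(object), -"time",
                                names_to = "component")
    ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                          scales = "free_y") +
      ggplot2::labs(x = "time", y = NULL)
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(.data[[vars[1]]], .data[[vars[2]]])) +
      ggplot2::geom_path() +
      ggplot2::labs(x = vars[1], y = vars[2])
  }
}

#' Plot a symbol sequence
#'
#' Oscillation amplitudes over time, colored by their S/M/L label, with the
#' classification thresholds drawn as horizontal lines.
#'
#' @param object A `symbol_sequence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symbol_sequence <- function(object, ...) {
  th <- attr(object, "thresholds")
  amax <- if (nrow(object)) max(object$amplitude) else 1
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$amplitude,
                               colour = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = amax * th, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time", y = "peak-to-trough amplitude",
                  colour = "label")
}

#' Plot a reaction-diffusion solution
#'
#' 1D solutions are drawn as a space-time heat map of `u`; 2D solutions as
#' a snapshot of the `u` field at the requested time (default: final
#' frame).
#'
#' @param object An `nhfhn_solution`.
#' @param time Snapshot time for 2D solutions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nhfhn_solution <- function(object, time = NULL, ...) {
  grid <- object$grid
  if (grid$dim == 1) {
    df <- as_tibble(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$time,
                                     fill = .data$u)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "x", y = "time", fill = "u")
  } else {
    if (is.null(time)) time <- max(object$times)
    k <- which.min(abs(object$times - time))
    df <- tibble(x = rep(grid$x, grid$ny),
                 y = rep(grid$y, each = grid$nx),
                 u = object$u[k, ])
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$u)) +
      ggplot2::geom_raster() +
      ggplot2::coord_equal() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(title = sprintf("u at t = %.4g", object$times[k]))
  }
}

#' Plot propagation diagnostics
#'
#' Per-location large-oscillation counts with the center reference and the
#' death-spot location (if any).
#'
#' @param object A `propagation_diagnostics` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.propagation_diagnostics <- function(object, ...) {
  g <- ggplot2::ggplot(object$by_location,
                       ggplot2::aes(.data$x, .data$n_large)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$center_count / 2,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "x", y = "large oscillations")
  if (!is.na(object$death_spot)) {
    g <- g + ggplot2::geom_vline(xintercept = c(-1, 1) * object$death_spot,
                                 colour = "red", linetype = "dotted")
  }
  g
}

#' Plot a stability sweep
#'
#' The Routh-Hurwitz margin and the real part of the complex eigenvalue
#' pair against the drive `I`; their common zero is the Hopf point.
#'
#' @param sweep A tibble from [stability_sweep()].
#' @return A ggplot object.
#' @export
plot_stability_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "I", "hurwitz_margin", "re_pair"),
    -"I", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$I, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "I", y = NULL)
}
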