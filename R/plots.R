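#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a swing/stance raster
#'
#' Step plot in the conventional style: swing black, stance white, limbs
#' stacked L1..R3 from top.
#' @param raster raster tibble (`frame`, `limb`, `swing`).
#' @param frame_rate frames per second (x axis in seconds).
#' @return ggplot object.
#' @export
plot_gait_raster <- function(raster, frame_rate = 150) {
  d <- dplyr::mutate(raster,
                     limb = factor(.data$limb, levels = rev(LIMBS)),
                     time_s = .data$frame / frame_rate,
                     state = factor(ifelse(.data$swing == 1, "swing", "stance"),
                                    levels = c("swing", "stance")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$limb,
                                  fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(swing = "black", stance = "white")) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = NULL) +
    ggplot2::theme_classic()
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble::tibble(v_par_mean = seq(max(min(object$data$v_par_mean), 0.5),
                                          max(object$data$v_par_mean),
                                          length.out = 200))
  grid$fit <- object$a_pl * grid$v_par_mean^object$b
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$v_par_mean, y = .data$stance_dur_ms)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::labs(
      x = "forward velocity (mm/s)", y = "stance duration (ms)",
      title = sprintf("tau = %.1f (v/v0)^%.3f, R^2 = %.2f",
                      object$a_pl, object$b, object$r_squared)) +
    ggplot2::theme_classic()
}

#' @export
autoplot.gait_fraction <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$speed_bin, y = .data$fraction,
                               fill = .data$template)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "forward velocity bin", y = "fraction best-matched") +
    ggplot2::theme_classic()
}

#' @export
autoplot.manifold_embedding <- function(object, colour = "freq_hz", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$e1, y = .data$e2,
                                       colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::theme_classic()
}

#' Plot relative-phase circular means across speed bins
#'
#' @param rel_phase tibble from [relative_phase_stats()].
#' @return ggplot object.
#' @export
plot_relative_phase <- function(rel_phase) {
  ggplot2::ggplot(rel_phase,
                  ggplot2::aes(x = .data$speed_bin, y = .data$mean,
                               group = .data$pair, colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "forward velocity bin",
                  y = "circular mean relative phase (cycles)") +
    ggplot2::theme_classic()
}

#' Plot turning modulation curves
#'
#' @param curves tibble from [turning_modulation_curves()].
#' @param parameter which kinematic parameter to show.
#' @return ggplot object.
#' @export
plot_modulation_curves <- function(curves, parameter = "stance_dur_ms") {
  d <- dplyr::filter(curves, .data$parameter == !!parameter)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$yaw_bin_center, y = .data$modulation,
                                  colour = .data$limb_role)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                                      fill = .data$limb_role),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "symmetrized yaw (deg/s)",
                  y = if (parameter == "step_dir_deg") "modulation (deg)"
                      else "modulation (%)") +
    ggplot2::theme_classic()
}
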