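#' Render model phases to limb positions
#'
#' Turns oscillator phases into limb-position time series so that model
#' output can be fed through the same pipeline as measured data. The
#' egocentric parallel position is `x_par = -A * cos(theta)` plus a
#' per-limb anteroposterior rest offset, so phase zero is the maximally
#' posterior point of the cycle and swing (phase < half a cycle) moves
#' the limb anteriorly; the perpendicular position is a constant
#' anatomical offset per limb. Camera-frame positions are built
#' kinematically: the foot is stationary during stance and advances by
#' one stride (`2A`) per cycle during swing, linearly in phase, which is
#' what makes camera-frame speed thresholding recover the model's own
#' swing/stance raster.
#'
#' @param model simulator output with `frame`, `limb` and unwrapped
#'   `theta` (rad); wrapped `phase` (cycles) is unwrapped per limb if
#'   `theta` is absent.
#' @param amplitude_mm oscillation amplitude `A`; peak-to-peak
#'   egocentric excursion is `2A`.
#' @param camera also produce camera-frame columns `x_cam`, `y_cam`?
#' @return limb table: `frame`, `limb`, `x_par`, `x_perp` (and
#'   `x_cam`, `y_cam`), in mm.
#' @export
render_limb_positions <- function(model, amplitude_mm = 1, camera = TRUE) {
  stopifnot(all(c("frame", "limb") %in% names(model)))
  if (!"theta" %in% names(model)) {
    model <- model |>
      dplyr::group_by(.data$limb) |>
      dplyr::arrange(.data$frame, .by_group = TRUE) |>
      dplyr::mutate(theta = signal::unwrap(cycles_to_rad(.data$phase))) |>
      dplyr::ungroup()
  }
  ap_rest <- c(L1 = 1.5, L2 = 0, L3 = -1.5, R1 = 1.5, R2 = 0, R3 = -1.5)
  lat_rest <- c(L1 = 1, L2 = 1.2, L3 = 1, R1 = -1, R2 = -1.2, R3 = -1)
  out <- model |>
    dplyr::mutate(
      x_par = -amplitude_mm * cos(.data$theta) + ap_rest[as.character(.data$limb)],
      x_perp = lat_rest[as.character(.data$limb)]
    )
  if (camera) {
    stride <- 2 * amplitude_mm
    w <- out$theta %% (2 * pi)
    ncyc <- floor(out$theta / (2 * pi))
    # smoothstep swing profile: brief acceleration from and deceleration
    # to rest with a fast mid-swing, as real swings have; the short
    # low-speed tails keep speed-threshold classification stable
    progress <- swing_progress(w)
    out$x_cam <- stride * (ncyc + progress) + ap_rest[as.character(out$limb)]
    out$y_cam <- lat_rest[as.character(out$limb)]
  }
  dplyr::select(out, "frame", "limb", dplyr::any_of(c("x_par", "x_perp", "x_cam", "y_cam")))
}

# camera-frame swing progress as a function of the within-cycle angle
# w in [0, 2*pi); swing spans w < pi
swing_progress <- function(w, edge = 0.06) {
  u <- pmin(pmax((w / pi - edge) / (1 - 2 * edge), 0), 1)
  ifelse(w < pi, 3 * u^2 - 2 * u^3, 1)
}
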