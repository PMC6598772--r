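#' Smooth body velocities with a zero-phase Gaussian kernel
#'
#' Centroid velocities oscillate within each stride because of the
#' periodicity of limb forces; longer-timescale path kinematics are
#' recovered by zero-phase (forward-backward) filtering with a Gaussian
#' kernel, by default with a standard deviation of 20 ms (three frames
#' at 150 frames/s).
#'
#' @param body body table (`frame`, `v_par`, `v_perp`, `v_rot`, ...).
#' @param sigma_ms kernel standard deviation in milliseconds.
#' @param frame_rate frames per second.
#' @param cols columns to smooth.
#' @return the body table with smoothed velocity columns and attribute
#'   `smoothed = TRUE`.
#' @export
smooth_body_velocities <- function(body, sigma_ms = 20, frame_rate = 150,
                                   cols = c("v_par", "v_perp", "v_rot")) {
  stopifnot(sigma_ms >= 0)
  if (any(diff(body$frame) != diff(body$frame)[1]))
    stop("non-uniform frame spacing", call. = FALSE)
  sigma_frames <- sigma_ms / 1000 * frame_rate
  out <- tibble::as_tibble(body)
  for (cl in intersect(cols, names(out))) {
    out[[cl]] <- gaussian_zero_phase(out[[cl]], sigma_frames)
  }
  attr(out, "smoothed") <- TRUE
  out
}

#' Classify frames as swing or stance
#'
#' A limb is in stance while its smoothed instantaneous speed in the
#' camera frame is below `speed_threshold` (default 20 mm/s, roughly the
#' positional measurement error per frame at 150 frames/s), and in swing
#' otherwise. Instantaneous speed is the frame-to-frame displacement
#' times the frame rate, smoothed with a centered moving average
#' (`avg_window` frames, shrinking at record edges).
#'
#' Camera-frame positions (`x_cam`, `y_cam`) are used when present;
#' otherwise the egocentric coordinates stand in for them.
#'
#' @param limbs limb table.
#' @param speed_threshold stance/swing speed threshold, mm/s.
#' @param avg_window moving-average window, frames (odd).
#' @param frame_rate frames per second.
#' @return tibble `frame`, `limb`, `swing` (1 = swing, 0 = stance),
#'   `speed` (smoothed, mm/s); attribute `threshold_used`.
#' @export
classify_swing_stance <- function(limbs, speed_threshold = 20, avg_window = 5,
                                  frame_rate = 150) {
  check_limb_df(limbs)
  stopifnot(speed_threshold > 0)
  use_cam <- all(c("x_cam", "y_cam") %in% names(limbs))
  xc <- if (use_cam) "x_cam" else "x_par"
  yc <- if (use_cam) "y_cam" else "x_perp"
  out <- limbs |>
    dplyr::group_by(.data$limb) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < avg_window) stop("record shorter than avg_window", call. = FALSE)
      dx <- diff(d[[xc]])
      dy <- diff(d[[yc]])
      sp <- sqrt(dx^2 + dy^2) * frame_rate
      sp <- c(sp, sp[length(sp)]) # displacement t -> t+1 assigned to frame t
      sp <- moving_average(sp, avg_window)
      tibble::tibble(frame = d$frame, speed = sp,
                     swing = as.integer(sp >= speed_threshold))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("frame", "limb", "swing", "speed") |>
    dplyr::arrange(.data$frame, .data$limb)
  attr(out, "threshold_used") <- speed_threshold
  out
}

#' Extract per-step kinematic parameters
#'
#' One row per complete swing + stance cycle (a swing run followed
#' immediately by a stance run of the same limb). Step length is the
#' camera-frame displacement between consecutive touchdown positions of
#' the limb; step direction is the angle of that displacement relative
#' to the body axis at touchdown (requires `heading` in `body` when
#' camera coordinates are used; with egocentric coordinates the
#' displacement is already body-referenced). Incomplete cycles at record
#' boundaries are dropped; an input with no swing events yields an empty
#' table.
#'
#' @param limbs limb table.
#' @param raster swing/stance table from [classify_swing_stance()].
#' @param body body table aligned to `limbs` (smoothed velocities).
#' @param frame_rate frames per second.
#' @return tibble with columns `limb`, `swing_start`, `swing_end`,
#'   `stance_start`, `stance_end` (frames), `swing_dur_ms`,
#'   `stance_dur_ms`, `step_length_mm`, `step_dir_deg`, `v_par_mean`,
#'   `yaw_mean` and, if present in the input, `fly_id`/`video`.
#' @export
extract_steps <- function(limbs, raster, body, frame_rate = 150) {
  check_limb_df(limbs)
  use_cam <- all(c("x_cam", "y_cam") %in% names(limbs))
  xc <- if (use_cam) "x_cam" else "x_par"
  yc <- if (use_cam) "y_cam" else "x_perp"
  has_heading <- "heading" %in% names(body)
  carry <- intersect(c("fly_id", "video"), names(limbs))
  ms_per_frame <- 1000 / frame_rate

  per_limb <- function(key) {
    lr <- raster[raster$limb == key, ]
    ld <- limbs[limbs$limb == key, ]
    runs <- logical_runs(lr$swing == 1)
    # complete cycles: swing run immediately followed by stance run,
    # with a known next touchdown for the step vector
    sw_idx <- which(runs$value)
    rows <- list()
    for (i in sw_idx) {
      if (i + 1 > nrow(runs) || runs$value[i + 1]) next
      if (i == 1) next # swing possibly truncated at the record start
      if (i + 1 == nrow(runs)) next # stance truncated at the record end
      td0 <- runs$start[i + 1] # touchdown closing this swing
      # next touchdown = start of the stance run after the *next* swing
      if (i + 3 > nrow(runs)) {
        td1 <- NA_integer_
      } else {
        td1 <- runs$start[i + 3]
      }
      fr <- lr$frame[runs$start[i]]:lr$frame[runs$end[i + 1]]
      bidx <- body$frame %in% fr
      dx <- if (!is.na(td1)) ld[[xc]][td1] - ld[[xc]][td0] else NA_real_
      dy <- if (!is.na(td1)) ld[[yc]][td1] - ld[[yc]][td0] else NA_real_
      len <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx)
      if (use_cam && has_heading && !is.na(ang)) {
        h <- body$heading[body$frame == lr$frame[td0]]
        if (length(h) == 1) ang <- ang - h
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        limb = key,
        swing_start = lr$frame[runs$start[i]],
        swing_end = lr$frame[runs$end[i]],
        stance_start = lr$frame[runs$start[i + 1]],
        stance_end = lr$frame[runs$end[i + 1]],
        swing_dur_ms = runs$length[i] * ms_per_frame,
        stance_dur_ms = runs$length[i + 1] * ms_per_frame,
        step_length_mm = len,
        step_dir_deg = ((ang * 180 / pi + 180) %% 360) - 180,
        v_par_mean = mean(body$v_par[bidx]),
        yaw_mean = if ("v_rot" %in% names(body)) mean(body$v_rot[bidx]) else NA_real_
      )
    }
    dplyr::bind_rows(rows)
  }

  steps <- dplyr::bind_rows(lapply(intersect(LIMBS, unique(as.character(raster$limb))),
                                   per_limb))
  if (nrow(steps) == 0) {
    steps <- tibble::tibble(
      limb = character(), swing_start = integer(), swing_end = integer(),
      stance_start = integer(), stance_end = integer(), swing_dur_ms = numeric(),
      stance_dur_ms = numeric(), step_length_mm = numeric(), step_dir_deg = numeric(),
      v_par_mean = numeric(), yaw_mean = numeric()
    )
  }
  if (length(carry) > 0 && nrow(steps) > 0) {
    ids <- limbs |> dplyr::distinct(dplyr::across(dplyr::all_of(carry)))
    if (nrow(ids) == 1) steps <- dplyr::bind_cols(steps, ids)
  }
  steps
}

#' Fit the stance-duration power law
#'
#' Nonlinear least-squares fit of `tau_stance = a_pl * (v_par / v0)^b`
#' with `v0 = 1` mm/s a fixed scaling velocity, so the prefactor `a_pl`
#' carries units of milliseconds and the exponent `b` is dimensionless.
#' R-squared is computed on the untransformed scale,
#' `1 - SS_res / SS_tot`.
#'
#' @param steps step table from [extract_steps()] (needs `stance_dur_ms`
#'   and `v_par_mean`), or any data frame with those columns.
#' @return an object of class `power_law_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
fit_stance_power_law <- function(steps) {
  d <- steps[is.finite(steps$stance_dur_ms) & is.finite(steps$v_par_mean) &
               steps$v_par_mean > 0, ]
  if (nrow(d) < 3) stop("need at least 3 steps with positive forward velocity",
                        call. = FALSE)
  if (length(unique(d$v_par_mean)) < 2)
    stop("exponent unidentifiable: all forward velocities equal", call. = FALSE)
  ols <- stats::lm(log(stance_dur_ms) ~ log(v_par_mean), data = d)
  start <- list(a_pl = exp(stats::coef(ols)[[1]]), b = stats::coef(ols)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(stance_dur_ms ~ a_pl * v_par_mean^b,
                      data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      # an exactly-fitting start can make the initial gradient singular;
      # nudge it off the solution
      minpack.lm::nlsLM(stance_dur_ms ~ a_pl * v_par_mean^b, data = d,
                        start = list(a_pl = start$a_pl * 0.98,
                                     b = start$b + 0.01),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    })
  pred <- stats::predict(fit)
  ss_res <- sum((d$stance_dur_ms - pred)^2)
  ss_tot <- sum((d$stance_dur_ms - mean(d$stance_dur_ms))^2)
  structure(
    list(fit = fit,
         a_pl = stats::coef(fit)[["a_pl"]],
         b = stats::coef(fit)[["b"]],
         v0 = 1,
         r_squared = 1 - ss_res / ss_tot,
         n = nrow(d),
         data = tibble::as_tibble(d[, c("v_par_mean", "stance_dur_ms")])),
    class = "power_law_fit"
  )
}

#' @method print power_law_fit
#' @export
print.power_law_fit <- function(x, ...) {
  cat("Stance-duration power law: tau_stance = a_pl * (v_par / 1 mm/s)^b\n")
  cat(sprintf("  a_pl = %.1f ms,  b = %.4f,  R^2 = %.3f  (n = %d steps)\n",
              x$a_pl, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, a_pl = x$a_pl, b = x$b,
                 nobs = x$n, sigma = summary(x$fit)$sigma)
}

#' Speed tercile presets
#'
#' Named forward-velocity bands used throughout the analyses: slow
#' (0-10.2 mm/s), medium (10.2-19 mm/s), fast (>19 mm/s).
#' @return tibble with `bin`, `lo`, `hi` (mm/s).
#' @export
speed_terciles <- function() {
  tibble::tibble(
    bin = factor(c("slow", "medium", "fast"), levels = c("slow", "medium", "fast")),
    lo = c(0, 10.2, 19),
    hi = c(10.2, 19, Inf)
  )
}

bin_speed <- function(v, terciles = speed_terciles()) {
  cut(v, breaks = c(terciles$lo, Inf), labels = terciles$bin, right = FALSE)
}

#' Stance-configuration summary
#'
#' Encodes each frame's stance configuration as a 6-bit string (order
#' L1 L2 L3 R1 R2 R3, 1 = stance), counts feet in stance, measures
#' per-configuration dwell times (contiguous frames in a configuration,
#' within contiguous walking bouts), and tabulates configuration and
#' feet-down-category probabilities against forward velocity. Frames
#' with `v_par` below `walking_threshold` (default 0.5 mm/s) are
#' excluded and break dwell-time runs.
#'
#' When counting the distinct configurations (`n_configs`),
#' `min_dwell_frames = 2` excludes configurations that only ever appear
#' as single-frame slivers; for continuous-time model output sampled at
#' the frame rate, nominally simultaneous transitions can straddle a
#' frame and leave such slivers, which are not configurations of the
#' underlying gait. The default (1) counts every code.
#'
#' @param raster swing/stance table from [classify_swing_stance()].
#' @param body aligned body table.
#' @param walking_threshold minimum forward speed, mm/s.
#' @param speed_bins tibble of speed bins as from [speed_terciles()].
#' @param frame_rate frames per second.
#' @param min_dwell_frames minimum maximal dwell (contiguous frames) for
#'   a code to count as a distinct configuration.
#' @return list of class `stance_config_summary`: `per_frame` (frame,
#'   config, feet_down, v_par, speed_bin), `dwell` (config, dwell times
#'   in frames and ms), `config_probs` (conditional probability of each
#'   configuration per speed bin), `category_probs` (feet-down counts
#'   per speed bin).
#' @export
stance_config_stats <- function(raster, body, walking_threshold = 0.5,
                                speed_bins = speed_terciles(), frame_rate = 150,
                                min_dwell_frames = 1) {
  wide <- raster |>
    dplyr::select("frame", "limb", "swing") |>
    tidyr::pivot_wider(names_from = "limb", values_from = "swing") |>
    dplyr::arrange(.data$frame)
  stopifnot(all(LIMBS %in% names(wide)))
  stance_mat <- 1L - as.matrix(wide[, LIMBS])
  config <- apply(stance_mat, 1, paste0, collapse = "")
  feet_down <- rowSums(stance_mat)
  v <- body$v_par[match(wide$frame, body$frame)]
  keep <- !is.na(v) & v >= walking_threshold
  per_frame <- tibble::tibble(
    frame = wide$frame, config = config, feet_down = feet_down,
    v_par = v, speed_bin = bin_speed(v, speed_bins)
  )[keep, ]

  # dwell times within contiguous walking bouts
  bout <- cumsum(c(TRUE, diff(per_frame$frame) != 1))
  r <- rle(paste(bout, per_frame$config))
  dwell <- tibble::tibble(
    config = sub("^\\S+ ", "", r$values),
    dwell_frames = r$lengths,
    dwell_ms = r$lengths * 1000 / frame_rate
  )

  config_probs <- per_frame |>
    dplyr::count(.data$speed_bin, .data$config) |>
    dplyr::group_by(.data$speed_bin) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  category_probs <- per_frame |>
    dplyr::count(.data$speed_bin, .data$feet_down) |>
    dplyr::group_by(.data$speed_bin) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  persistent <- dwell |>
    dplyr::group_by(.data$config) |>
    dplyr::summarise(max_dwell = max(.data$dwell_frames), .groups = "drop") |>
    dplyr::filter(.data$max_dwell >= min_dwell_frames)

  structure(
    list(per_frame = per_frame, dwell = dwell, config_probs = config_probs,
         category_probs = category_probs,
         n_configs = nrow(persistent),
         configs = sort(persistent$config)),
    class = "stance_config_summary"
  )
}

#' @method print stance_config_summary
#' @export
print.stance_config_summary <- function(x, ...) {
  cat("Stance-configuration summary:", nrow(x$per_frame), "walking frames,",
      x$n_configs, "distinct configurations\n")
  invisible(x)
}
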