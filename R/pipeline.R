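#' Read per-frame kinematic tables
#'
#' Reads a delimited table with one row per frame (`frame`, optional
#' `fly_id`/`video`, body columns `v_par`, `v_perp`, `v_rot`, optional
#' `heading`, and limb columns `L1_x`, `L1_y`, ..., `R3_x`, `R3_y` in mm
#' egocentric, optionally `L1_xcam`/`L1_ycam`, ...) and splits it into
#' the package's long limb table and body table.
#'
#' @param path CSV file path.
#' @return list with `limbs` and `body` tibbles.
#' @export
read_frame_csv <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  body_cols <- intersect(c("frame", "fly_id", "video", "v_par", "v_perp",
                           "v_rot", "heading"), names(raw))
  body <- raw[, body_cols]
  limbs <- purrr::map_dfr(LIMBS, function(l) {
    out <- tibble::tibble(frame = raw$frame, limb = l,
                          x_par = raw[[paste0(l, "_x")]],
                          x_perp = raw[[paste0(l, "_y")]])
    xc <- paste0(l, "_xcam")
    yc <- paste0(l, "_ycam")
    if (all(c(xc, yc) %in% names(raw))) {
      out$x_cam <- raw[[xc]]
      out$y_cam <- raw[[yc]]
    }
    for (cl in intersect(c("fly_id", "video"), names(raw))) out[[cl]] <- raw[[cl]]
    out
  }) |> dplyr::arrange(.data$frame, .data$limb)
  list(limbs = limbs, body = body)
}

#' Write per-frame kinematic tables
#'
#' Inverse of [read_frame_csv()]: joins a limb table and body table into
#' one wide per-frame CSV.
#' @param limbs,body long limb table and body table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(limbs, body, path) {
  wide <- body
  for (l in LIMBS) {
    d <- limbs[limbs$limb == l, ]
    d <- d[match(body$frame, d$frame), ]
    wide[[paste0(l, "_x")]] <- d$x_par
    wide[[paste0(l, "_y")]] <- d$x_perp
    if ("x_cam" %in% names(d)) {
      wide[[paste0(l, "_xcam")]] <- d$x_cam
      wide[[paste0(l, "_ycam")]] <- d$y_cam
    }
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' All thresholds default to the reference values used throughout:
#' swing/stance speed threshold 20 mm/s, walking filter 0.5 mm/s,
#' perturbation selection 5 mm/s pre-event and 0.1 mm/s post-event,
#' speed terciles at 10.2 and 19 mm/s, 100 ms embedding half-window.
#'
#' @param ... overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  utils::modifyList(list(
    frame_rate = 150,
    swing_threshold = 20,
    avg_window = 5,
    walking_threshold = 0.5,
    smoothing_sigma_ms = 20,
    sg_order = 3,
    sg_window = 15,
    half_window_ms = 100,
    n_segments = 1000,
    embed = FALSE,
    min_pre_speed = 5,
    min_post_speed = 0.1,
    seed = 1
  ), list(...))
}

#' Run the full coordination-analysis pipeline
#'
#' Executes, in order: body-velocity smoothing, swing/stance
#' classification, step extraction, stance-duration power law (when the
#' speed range permits), stance-configuration statistics, phase
#' estimation, relative-phase statistics, feet-down-versus-phase,
#' template coherence/best-gait fractions, and optionally segment
#' embedding. Each stage's output lands in the returned bundle; when
#' `out_dir` is given, tables are also written as CSV together with a
#' JSON echo of the resolved configuration.
#'
#' @param limbs limb table (or a `walking_scenario`/`canonical_gait_sim`
#'   object, from which limbs and body are taken).
#' @param body body table (ignored when `limbs` carries one).
#' @param config list from [default_config()].
#' @param out_dir optional output directory.
#' @return list of class `gait_pipeline` with elements `raster`,
#'   `steps`, `power_law`, `config_stats`, `phase`, `rel_phase`,
#'   `feet_down`, `gait_fractions`, `embedding` (or `NULL`), `config`.
#' @export
run_pipeline <- function(limbs, body = NULL, config = default_config(),
                         out_dir = NULL) {
  if (inherits(limbs, "walking_scenario")) {
    body <- limbs$body
    limbs <- limbs$limbs
  } else if (inherits(limbs, "canonical_gait_sim")) {
    n <- max(limbs$limbs$frame)
    body <- tibble::tibble(frame = seq_len(n),
                           v_par = rep(15, n), v_perp = 0, v_rot = 0)
    limbs <- limbs$limbs
  }
  if (is.null(body)) stop("a body table is required", call. = FALSE)
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  body_s <- stage("smooth_body", smooth_body_velocities(
    body, sigma_ms = cfg$smoothing_sigma_ms, frame_rate = cfg$frame_rate))
  raster <- stage("classify", classify_swing_stance(
    limbs, speed_threshold = cfg$swing_threshold, avg_window = cfg$avg_window,
    frame_rate = cfg$frame_rate))
  steps <- stage("steps", extract_steps(limbs, raster, body_s,
                                        frame_rate = cfg$frame_rate))
  power_law <- NULL
  vv <- steps$v_par_mean[steps$v_par_mean > 0]
  if (nrow(steps) >= 3 && length(unique(round(vv, 6))) >= 3 &&
      stats::sd(vv) > 0.5) {
    power_law <- stage("power_law", fit_stance_power_law(steps))
  }
  config_stats <- stage("config_stats", stance_config_stats(
    raster, body_s, walking_threshold = cfg$walking_threshold,
    frame_rate = cfg$frame_rate))
  phase <- stage("phase", estimate_phase(
    limbs, sg_order = cfg$sg_order, sg_window = cfg$sg_window,
    frame_rate = cfg$frame_rate))
  rel_phase <- stage("rel_phase", relative_phase_stats(
    phase, body_s, walking_threshold = cfg$walking_threshold))
  feet_down <- stage("feet_down", feet_down_vs_phase(
    raster, phase, body = body_s, walking_threshold = cfg$walking_threshold))
  gait_fractions <- stage("coherence", best_gait_fraction(
    phase, body_s, walking_threshold = cfg$walking_threshold))
  embedding <- NULL
  if (isTRUE(cfg$embed)) {
    segs <- stage("segments", build_segments(
      limbs, half_window_ms = cfg$half_window_ms, n_samples = cfg$n_segments,
      seed = cfg$seed, frame_rate = cfg$frame_rate, phase = phase,
      raster = raster))
    embedding <- stage("embedding", embed_manifold(segs, seed = cfg$seed))
  }

  out <- structure(list(
    raster = raster, steps = steps, power_law = power_law,
    config_stats = config_stats, phase = phase, rel_phase = rel_phase,
    feet_down = feet_down, gait_fractions = gait_fractions,
    embedding = embedding, config = cfg
  ), class = "gait_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(steps, file.path(out_dir, "steps.csv"), row.names = FALSE)
    utils::write.csv(raster, file.path(out_dir, "raster.csv"), row.names = FALSE)
    utils::write.csv(phase, file.path(out_dir, "phase.csv"), row.names = FALSE)
    utils::write.csv(rel_phase, file.path(out_dir, "relative_phase.csv"),
                     row.names = FALSE)
    utils::write.csv(config_stats$config_probs,
                     file.path(out_dir, "stance_configs.csv"), row.names = FALSE)
    utils::write.csv(gait_fractions$summary,
                     file.path(out_dir, "gait_fractions.csv"), row.names = FALSE)
    if (!is.null(embedding))
      utils::write.csv(embedding, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

#' @method print gait_pipeline
#' @export
print.gait_pipeline <- function(x, ...) {
  cat("Gait analysis pipeline:", nrow(x$steps), "steps,",
      x$config_stats$n_configs, "stance configurations\n")
  invisible(x)
}

#' Generate the deterministic fixture bundle
#'
#' Builds the synthetic datasets used by the test-suite and examples: a
#' six-limb-model stance-duration sweep, the three canonical gaits from
#' the Hopf simulator, one turning scenario and one perturbation
#' scenario. `scale = "small"` keeps every piece short;
#' `scale = "paper"` uses the reference stance-duration range and
#' tripod stepping frequencies uniform in 5-12.5 Hz at full durations.
#'
#' @param seed RNG seed.
#' @param scale `"small"` or `"paper"`.
#' @return named list: `sweep` (list of model runs by tau_stance),
#'   `gaits` (list of `canonical_gait_sim`), `turning`, `perturbation`
#'   (both `walking_scenario`), `metadata` (every generative parameter).
#' @export
generate_fixtures <- function(seed = 7, scale = c("small", "paper")) {
  scale <- match.arg(scale)
  small <- scale == "small"
  taus <- if (small) c(40, 80, 150, 210) else seq(40, 210, length.out = 10)
  dur <- if (small) 3 else 5
  sweep <- purrr::map(taus, function(ts) {
    simulate_six_limb_model(tau_stance = ts, duration_s = dur, seed = seed)
  })
  names(sweep) <- paste0("tau", taus)
  gaits <- purrr::map(c("tripod", "left_tetrapod", "wave"), function(g) {
    simulate_canonical_gait(g, duration_s = if (small) 3 else 5, seed = seed)
  })
  names(gaits) <- c("tripod", "left_tetrapod", "wave")
  turning <- synth_behavior_generator(list(
    duration_s = if (small) 15 else 40, tau_stance = 55,
    turns = list(n = if (small) 4 else 10, peak_yaw = 300, width_ms = 300,
                 modulation = list(stance_dur = c(I2 = 0.2, I3 = 0.2,
                                                  O2 = -0.1, O3 = -0.1),
                                   swing_dur = c(I2 = -0.15, I3 = -0.15),
                                   step_length = c(O1 = 0.15, O2 = 0.15,
                                                   O3 = 0.15, I2 = -0.15,
                                                   I3 = -0.15),
                                   step_dir = c(I1 = 30)))
  ), seed = seed)
  perturbation <- synth_behavior_generator(list(
    duration_s = if (small) 15 else 40, tau_stance = 60,
    perturbations = list(times_s = if (small) c(4, 8, 12) else seq(4, 36, by = 4),
                         tau_stance_new = 90, hold_ms = 400)
  ), seed = seed + 1)
  list(
    sweep = sweep, gaits = gaits, turning = turning, perturbation = perturbation,
    metadata = list(
      seed = seed, scale = scale, tau_stance_sweep = taus,
      tau_swing = 40, alpha = 0.125,
      sweep_duration_s = dur,
      gait_stepping_freq = "tripod-equivalent uniform 5-12.5 Hz",
      turning = turning$scenario, perturbation = perturbation$scenario
    )
  )
}
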