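#' Generate ground-truth-labelled walking scenarios
#'
#' Synthetic stand-in for turning and perturbation recordings: a
#' six-limb phase-model walk at a baseline stance duration, on which the
#' scenario imposes (a) turning episodes - Gaussian yaw-rate pulses with
#' limb-specific, yaw-proportional modulations of swing/stance duration,
#' step length and step direction for the inside/outside limbs,
#' optionally locked to a reference limb phase - and (b) slowing
#' perturbations - a step increase of stance duration across all limbs
#' at event onset, held for a fixed interval. All imposed modulations
#' are returned as ground truth, so downstream analyses can be checked
#' for parameter recovery.
#'
#' Scenario fields (all optional except none): `duration_s` (default
#' 20), `tau_stance` (ms, 60), `tau_swing` (40), `alpha` (1/8),
#' `amplitude_mm` (1), `frame_rate` (150), `noise_sd_mm` (0),
#' `turns = list(n, peak_yaw, width_ms, first_side, alternate,
#' phase_lock = list(limb, phase), modulation = list(stance_dur =
#' c(I3 = 0.3, ...), swing_dur = ..., step_length = ..., step_dir =
#' ...))` (fractional gains at peak yaw; `step_dir` in degrees), and
#' `perturbations = list(times_s, tau_stance_new, hold_ms)`.
#'
#' @param scenario named list as above.
#' @param seed RNG seed.
#' @return list of class `walking_scenario`: `limbs` (limb table with
#'   camera coordinates), `body` (with `v_par`, `v_rot`, `heading`),
#'   `events` (type, frame, side, parameters), `truth` (list: `phase`
#'   table, `raster`, per-frame modulation schedules), `scenario`
#'   (resolved config).
#' @export
synth_behavior_generator <- function(scenario = list(), seed = 1) {
  sc <- utils::modifyList(list(
    duration_s = 20, tau_stance = 60, tau_swing = 40, alpha = 1 / 8,
    amplitude_mm = 1, frame_rate = 150, noise_sd_mm = 0,
    turns = NULL, perturbations = NULL
  ), scenario)
  validate_scenario(sc)
  fr <- sc$frame_rate
  n <- round(sc$duration_s * fr)
  dt <- 0.025
  thin <- round(1000 / fr / dt)
  n_steps <- n * thin

  theta0 <- withr::with_seed(derive_seed(seed, "scenario"), stats::runif(6, 0, 2 * pi))
  # settle on the baseline coordination pattern before the record starts
  settle <- .sixlimb_integrate(theta0, sc$tau_swing, sc$tau_stance, sc$alpha,
                               dt, 10000 * 40, 40000, TRUE)
  th_start <- settle[nrow(settle), ]

  # --- turning episodes -------------------------------------------------
  yaw <- numeric(n + 1)
  sides <- character(0)
  turn_frames <- integer(0)
  if (!is.null(sc$turns)) {
    tu <- utils::modifyList(list(
      n = 4, peak_yaw = 300, width_ms = 250, first_side = "left",
      alternate = TRUE, phase_lock = NULL, modulation = list()
    ), sc$turns)
    sc$turns <- tu
    turn_frames <- round(seq(0.15, 0.85, length.out = tu$n) * n)
    sides <- rep(c(tu$first_side, setdiff(c("left", "right"), tu$first_side)),
                 length.out = tu$n)
    if (!tu$alternate) sides <- rep(tu$first_side, tu$n)
    if (!is.null(tu$phase_lock)) {
      # unmodulated pre-pass from the same initial state finds frames
      # where the reference limb crosses the target phase near each
      # nominal event time
      ones0 <- matrix(1, n + 1, 6)
      pre <- .sixlimb_integrate_modulated(th_start, sc$tau_swing, sc$tau_stance,
                                          sc$alpha, dt, n_steps, thin,
                                          ones0, ones0)
      li <- match(tu$phase_lock$limb, LIMBS)
      refp <- rad_to_cycles(pre[, li])
      hits <- which(abs(circ_dist(refp, tu$phase_lock$phase)) < 0.02)
      turn_frames <- vapply(turn_frames, function(f) {
        hits[which.min(abs(hits - f))]
      }, numeric(1))
    }
    sigma_f <- tu$width_ms / 1000 * fr / 2.355 # width is FWHM
    for (i in seq_along(turn_frames)) {
      bump <- exp(-((seq_len(n + 1) - turn_frames[i])^2) / (2 * sigma_f^2))
      yaw <- yaw + bump * tu$peak_yaw * ifelse(sides[i] == "left", 1, -1)
    }
  }

  # --- per-limb duration schedules -------------------------------------
  ones <- matrix(1, n + 1, 6)
  sched_sw <- ones
  sched_st <- ones
  lat <- substr(LIMBS, 1, 1)
  seg <- substr(LIMBS, 2, 2)
  gain_of <- function(mod, role) if (!is.null(mod) && role %in% names(mod)) mod[[role]] else 0
  if (!is.null(sc$turns)) {
    mod <- sc$turns$modulation
    rel <- abs(yaw) / sc$turns$peak_yaw
    inside_left <- yaw >= 0 # inside side is the turn side
    for (i in 1:6) {
      role_when_left <- paste0(ifelse(lat[i] == "L", "I", "O"), seg[i])
      role_when_right <- paste0(ifelse(lat[i] == "R", "I", "O"), seg[i])
      g_st <- ifelse(inside_left, gain_of(mod$stance_dur, role_when_left),
                     gain_of(mod$stance_dur, role_when_right))
      g_sw <- ifelse(inside_left, gain_of(mod$swing_dur, role_when_left),
                     gain_of(mod$swing_dur, role_when_right))
      sched_st[, i] <- 1 + g_st * rel
      sched_sw[, i] <- 1 + g_sw * rel
    }
  }
  pert_events <- integer(0)
  if (!is.null(sc$perturbations)) {
    pe <- utils::modifyList(list(times_s = numeric(0), tau_stance_new = 90,
                                 hold_ms = 400), sc$perturbations)
    sc$perturbations <- pe
    mult <- pe$tau_stance_new / sc$tau_stance
    pert_events <- round(pe$times_s * fr)
    for (f0 in pert_events) {
      f1 <- min(n + 1, f0 + round(pe$hold_ms / 1000 * fr))
      sched_st[f0:f1, ] <- sched_st[f0:f1, ] * mult
    }
  }

  theta <- .sixlimb_integrate_modulated(th_start, sc$tau_swing, sc$tau_stance,
                                        sc$alpha, dt, n_steps, thin,
                                        sched_sw, sched_st)

  # --- rendering with per-limb step-length/direction modulation --------
  len_gain <- ones - 1
  dir_shift <- ones - 1
  if (!is.null(sc$turns)) {
    mod <- sc$turns$modulation
    rel <- abs(yaw) / sc$turns$peak_yaw
    inside_left <- yaw >= 0
    for (i in 1:6) {
      rl <- paste0(ifelse(lat[i] == "L", "I", "O"), seg[i])
      rr <- paste0(ifelse(lat[i] == "R", "I", "O"), seg[i])
      len_gain[, i] <- ifelse(inside_left, gain_of(mod$step_length, rl),
                              gain_of(mod$step_length, rr)) * rel
      dshift <- ifelse(inside_left, gain_of(mod$step_dir, rl),
                       gain_of(mod$step_dir, rr)) * rel
      # mirror the imposed direction for right turns so that the
      # symmetrized analysis sees a consistent sign
      dir_shift[, i] <- ifelse(inside_left, dshift, -dshift)
    }
  }

  A <- sc$amplitude_mm
  ap_rest <- c(L1 = 1.5, L2 = 0, L3 = -1.5, R1 = 1.5, R2 = 0, R3 = -1.5)
  lat_rest <- c(L1 = 1, L2 = 1.2, L3 = 1, R1 = -1, R2 = -1.2, R3 = -1)
  limb_tbl <- purrr::map_dfr(1:6, function(i) {
    th <- theta[, i]
    Ai <- A * (1 + len_gain[, i])
    x_par <- -Ai * cos(th) + ap_rest[i]
    w <- th %% (2 * pi)
    prog <- swing_progress(w)
    ncyc <- floor(th / (2 * pi))
    # cumulative camera path: stride and direction fixed per cycle at
    # that cycle's first frame
    cyc_id <- ncyc - min(ncyc) + 1L
    first_idx <- match(unique(cyc_id), cyc_id)
    stride_c <- 2 * Ai[first_idx]
    dir_c <- dir_shift[first_idx, i] * pi / 180
    cum_x <- cumsum(c(0, stride_c * cos(dir_c)))
    cum_y <- cumsum(c(0, stride_c * sin(dir_c)))
    x_cam <- cum_x[cyc_id] + stride_c[cyc_id] * cos(dir_c[cyc_id]) * prog +
      ap_rest[i]
    y_cam <- cum_y[cyc_id] + stride_c[cyc_id] * sin(dir_c[cyc_id]) * prog +
      lat_rest[i]
    tibble::tibble(frame = seq_len(length(th)), limb = LIMBS[i],
                   x_par = x_par, x_perp = lat_rest[i],
                   x_cam = x_cam, y_cam = y_cam,
                   theta = th)
  })
  if (sc$noise_sd_mm > 0) {
    limb_tbl <- withr::with_seed(derive_seed(seed, "scenario") + 3L, {
      dplyr::mutate(limb_tbl, dplyr::across(
        c("x_par", "x_perp", "x_cam", "y_cam"),
        function(v) v + stats::rnorm(length(v), sd = sc$noise_sd_mm)))
    })
  }

  tau_eff <- sc$tau_stance * rowMeans(sched_st)
  body <- tibble::tibble(
    frame = seq_len(n + 1),
    v_par = stance_to_speed(tau_eff),
    v_perp = 0,
    v_rot = yaw,
    heading = cumsum(yaw * pi / 180) / fr
  )

  events <- dplyr::bind_rows(
    if (length(turn_frames) > 0)
      tibble::tibble(type = "turn", frame = as.integer(turn_frames), side = sides,
                     peak_yaw = sc$turns$peak_yaw),
    if (length(pert_events) > 0)
      tibble::tibble(type = "perturbation", frame = as.integer(pert_events),
                     side = NA_character_,
                     peak_yaw = NA_real_)
  )
  truth <- list(
    phase = tibble::tibble(frame = rep(seq_len(n + 1), 6),
                           limb = rep(LIMBS, each = n + 1),
                           phase = rad_to_cycles(as.vector(theta)),
                           freq_hz = 1000 / (sc$tau_swing + sc$tau_stance)) |>
      dplyr::arrange(.data$frame, .data$limb),
    raster = tibble::tibble(frame = rep(seq_len(n + 1), 6),
                            limb = rep(LIMBS, each = n + 1),
                            swing = as.integer((as.vector(theta) %% (2 * pi)) < pi)) |>
      dplyr::arrange(.data$frame, .data$limb),
    sched_swing = sched_sw, sched_stance = sched_st,
    len_gain = len_gain, dir_shift = dir_shift
  )
  structure(list(limbs = dplyr::select(limb_tbl, -"theta"), body = body,
                 events = events, truth = truth, scenario = sc, seed = seed),
            class = "walking_scenario")
}

validate_scenario <- function(sc) {
  stopifnot(sc$duration_s > 0, sc$tau_stance > 0, sc$tau_swing > 0,
            sc$amplitude_mm > 0)
  if (!is.null(sc$turns) && !is.null(sc$turns$width_ms) && sc$turns$width_ms <= 0)
    stop("turn width must be positive", call. = FALSE)
  if (!is.null(sc$perturbations)) {
    pe <- sc$perturbations
    if (!is.null(pe$hold_ms) && pe$hold_ms <= 0)
      stop("perturbation hold must be positive", call. = FALSE)
    if (!is.null(pe$tau_stance_new) && pe$tau_stance_new <= 0)
      stop("perturbed stance duration must be positive", call. = FALSE)
  }
  invisible(sc)
}

#' Map stance duration to forward speed
#'
#' Inverse of the stance-duration power law `tau = a_pl * v^b` with the
#' reference parameters `a_pl = 932.8` ms, `b = -1.025`; used only to
#' give model output a plausible forward-velocity axis.
#' @param tau_ms stance durations, ms.
#' @param a_pl,b power-law parameters.
#' @return forward velocity, mm/s.
#' @export
stance_to_speed <- function(tau_ms, a_pl = 932.8, b = -1.025) {
  (tau_ms / a_pl)^(1 / b)
}

#' @method print walking_scenario
#' @export
print.walking_scenario <- function(x, ...) {
  cat(sprintf("Synthetic walking scenario: %.0f s at tau_stance = %g ms, %d events\n",
              x$scenario$duration_s, x$scenario$tau_stance,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}
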