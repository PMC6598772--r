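#' Simulate the one-parameter six-limb phase model
#'
#' Integrates six coupled piecewise-linear phase oscillators (limb order
#' L1, L2, L3, R1, R2, R3). Each limb's phase advances at `pi/tau_swing`
#' in swing (phase < pi mod 2pi) and `pi/tau_stance` in stance; a limb's
#' swing advance is divisively halved while its posterior ipsilateral
#' neighbour is also in swing, which produces posterior-to-anterior
#' metachronal waves; contralateral pairs are held in antiphase by a
#' divisive `alpha * sin(theta_contra - theta)` term. Stance duration is
#' the model's single speed-controlling parameter.
#'
#' Integration is fixed-step Heun (second-order Runge-Kutta) with the
#' swing/stance indicators evaluated at each stage point;
#' `simulate_rule_based()` runs the forward-Euler variant, which is the
#' discrete-time rule-based formulation of the same dynamics. The
#' integrator refuses timesteps above `min(tau_swing, tau_stance)/20`.
#'
#' @param tau_stance stance duration, ms (40-210 covers slow to fast
#'   walking).
#' @param tau_swing swing duration, ms.
#' @param alpha cross-body coupling strength in (0, 1).
#' @param dt integration timestep, ms.
#' @param duration_s simulated time, seconds (after the transient).
#' @param transient_s initial interval discarded before output.
#' @param frame_rate output sampling rate, frames/s.
#' @param theta0 six initial phases (rad); `NULL` uses `init`.
#' @param init initial configuration when `theta0` is `NULL`:
#'   `"wave"` starts on the contiguous metachronal wave (each limb's
#'   swing begins as its posterior neighbour's ends, contralateral sides
#'   in antiphase, with a seeded common offset), which is the
#'   configuration reached by slowly varying stance duration from the
#'   tripod solution; `"random"` draws uniformly on `[0, 2pi)`. The
#'   ipsilateral coupling only delays a limb whose swing overlaps its
#'   posterior neighbour's, so once swings separate their lag is frozen:
#'   random starts leave seed-dependent lags at long stance durations,
#'   while the wave start gives the single-parameter family the model is
#'   built around.
#' @param seed RNG seed for the initial condition.
#' @return tibble `frame`, `limb`, `theta` (unwrapped rad), `phase`
#'   (cycles in `[0,1)`), `swing` (1 = swing); attributes `params` and
#'   `frame_rate`. Stepping frequency is `1000 / (tau_swing +
#'   tau_stance)` Hz.
#' @export
simulate_six_limb_model <- function(tau_stance = 40, tau_swing = 40, alpha = 1 / 8,
                                    dt = 0.025, duration_s = 5, transient_s = 10,
                                    frame_rate = 150, theta0 = NULL,
                                    init = c("wave", "random"), seed = 1) {
  stopifnot(alpha > 0, alpha < 1, tau_stance > 0, tau_swing > 0, dt > 0)
  sixlimb_run(tau_stance, tau_swing, alpha, dt, duration_s, transient_s,
              frame_rate, theta0, match.arg(init), seed, heun = TRUE)
}

#' @rdname simulate_six_limb_model
#' @export
simulate_rule_based <- function(tau_stance = 40, tau_swing = 40, alpha = 1 / 8,
                                dt = 0.025, duration_s = 5, transient_s = 10,
                                frame_rate = 150, theta0 = NULL,
                                init = c("wave", "random"), seed = 1) {
  sixlimb_run(tau_stance, tau_swing, alpha, dt, duration_s, transient_s,
              frame_rate, theta0, match.arg(init), seed, heun = FALSE)
}

# contiguous metachronal wave: each limb's swing onset coincides with
# its posterior neighbour's swing end; contralateral antiphase
wave_init <- function(tau_swing, tau_stance, seed) {
  frac <- tau_swing / (tau_swing + tau_stance)
  left <- c(-2, -1, 0) * 2 * pi * frac # L1, L2, L3
  offset <- withr::with_seed(derive_seed(seed, "sixlimb"),
                             stats::runif(1, 0, 2 * pi))
  (c(left, left + pi) + offset) %% (2 * pi)
}

sixlimb_run <- function(tau_stance, tau_swing, alpha, dt, duration_s, transient_s,
                        frame_rate, theta0, init, seed, heun) {
  if (is.null(theta0)) {
    theta0 <- if (init == "wave") {
      wave_init(tau_swing, tau_stance, seed)
    } else {
      withr::with_seed(derive_seed(seed, "sixlimb"),
                       stats::runif(6, 0, 2 * pi))
    }
  }
  stopifnot(length(theta0) == 6)
  ms_total <- (duration_s + transient_s) * 1000
  thin <- round(1000 / frame_rate / dt) # steps per output frame
  n_steps <- ceiling(ms_total / dt)
  n_steps <- (n_steps %/% thin) * thin
  theta <- .sixlimb_integrate(theta0, tau_swing, tau_stance, alpha, dt,
                              n_steps, thin, heun)
  n_frames <- nrow(theta)
  drop <- round(transient_s * frame_rate)
  keep <- seq(drop + 1L, n_frames)
  th <- as.vector(theta[keep, ])
  out <- tibble::tibble(
    frame = rep(seq_along(keep), times = 6),
    limb = rep(LIMBS, each = length(keep)),
    theta = th,
    phase = rad_to_cycles(th),
    swing = as.integer((th %% (2 * pi)) < pi)
  ) |>
    dplyr::arrange(.data$frame, .data$limb)
  attr(out, "params") <- list(
    tau_stance = tau_stance, tau_swing = tau_swing, alpha = alpha, dt = dt,
    duration_s = duration_s, transient_s = transient_s, theta0 = theta0,
    method = if (heun) "heun" else "euler",
    stepping_freq_hz = 1000 / (tau_swing + tau_stance)
  )
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Swing/stance raster from model phases
#'
#' Converts simulator output (a table with `frame`, `limb` and either
#' `swing` or `phase`) to the raster schema used by the kinematic
#' analyses, taking the model's own swing indicator as ground truth.
#' When the indicator is absent it is reconstructed from the phase with
#' swing occupying the fraction `1 - beta` of the cycle from phase zero.
#' @param model simulator output tibble.
#' @param beta duty factor used when no `swing` column is present.
#' @return tibble `frame`, `limb`, `swing`.
#' @export
model_raster <- function(model, beta = 0.5) {
  if (!"swing" %in% names(model)) {
    model$swing <- as.integer((model$phase %% 1) < 1 - beta)
  }
  dplyr::select(model, "frame", "limb", "swing")
}

#' Phase table from simulator output
#'
#' Reshapes simulator ground-truth phases into the schema produced by
#' [estimate_phase()], attaching the stepping frequency implied by the
#' model parameters.
#' @param model simulator output tibble.
#' @param frame_rate frames per second (defaults to the stored
#'   attribute).
#' @return tibble `frame`, `limb`, `phase`, `freq_hz`.
#' @export
model_phase <- function(model, frame_rate = NULL) {
  if ("freq_hz" %in% names(model)) {
    f <- model$freq_hz
  } else {
    p <- attr(model, "params")
    f <- if (!is.null(p)) p$stepping_freq_hz else NA_real_
  }
  tibble::tibble(frame = model$frame, limb = model$limb,
                 phase = model$phase %% 1, freq_hz = f)
}

#' Simulate a continuous stance-duration sweep
#'
#' Runs the six-limb model while ramping the stance duration linearly
#' across `tau_range`, so stepping frequency varies continuously as it
#' does across walking bouts. This is the reference input for manifold
#' embedding: a continuum of coordination patterns rather than a few
#' discrete stance durations.
#'
#' @param tau_range stance-duration range (ms), swept linearly in time.
#' @param duration_s swept interval, s.
#' @param tau_swing swing duration, ms.
#' @param alpha cross-body coupling strength.
#' @param frame_rate output sampling rate, frames/s.
#' @param seed RNG seed for the initial condition.
#' @param dt integration timestep, ms.
#' @return tibble as from [simulate_six_limb_model()] with an additional
#'   `tau_stance` column; `freq_hz` per frame is `1000 / (tau_swing +
#'   tau_stance)`.
#' @export
simulate_stance_sweep <- function(tau_range = c(45, 180), duration_s = 60,
                                  tau_swing = 40, alpha = 1 / 8,
                                  frame_rate = 150, seed = 1, dt = 0.025) {
  n <- round(duration_s * frame_rate)
  thin <- round(1000 / frame_rate / dt)
  mult <- seq(tau_range[1], tau_range[2], length.out = n + 1) / tau_range[1]
  sched_st <- matrix(mult, n + 1, 6)
  sched_sw <- matrix(1, n + 1, 6)
  theta0 <- wave_init(tau_swing, tau_range[1], seed)
  settle <- .sixlimb_integrate(theta0, tau_swing, tau_range[1], alpha, dt,
                               400000, 400000, TRUE)
  theta <- .sixlimb_integrate_modulated(settle[nrow(settle), ], tau_swing,
                                        tau_range[1], alpha, dt, n * thin, thin,
                                        sched_sw, sched_st)
  th <- as.vector(theta)
  tau_frame <- tau_range[1] * mult
  out <- tibble::tibble(
    frame = rep(seq_len(n + 1), 6),
    limb = rep(LIMBS, each = n + 1),
    theta = th,
    phase = rad_to_cycles(th),
    swing = as.integer((th %% (2 * pi)) < pi),
    tau_stance = rep(tau_frame, 6),
    freq_hz = 1000 / (tau_swing + rep(tau_frame, 6))
  ) |>
    dplyr::arrange(.data$frame, .data$limb)
  attr(out, "params") <- list(tau_range = tau_range, tau_swing = tau_swing,
                              alpha = alpha, dt = dt, duration_s = duration_s,
                              method = "heun_modulated")
  attr(out, "frame_rate") <- frame_rate
  out
}
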