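# Duty-factor warp between the uniform (time-fraction) phase u of a limb
# cycle and the oscillator plane angle. Swing (angle in [0, pi)) occupies
# the time fraction (1 - beta); stance the fraction beta.
warp_uniform_to_angle <- function(u, beta) {
  u <- u %% 1
  ifelse(u < 1 - beta, pi * u / (1 - beta), pi + pi * (u - (1 - beta)) / beta)
}

warp_angle_to_uniform <- function(theta, beta) {
  theta <- theta %% (2 * pi)
  ifelse(theta < pi, (1 - beta) * theta / pi,
         (1 - beta) + beta * (theta - pi) / pi)
}

#' Duty factors of the canonical gaits
#'
#' Tripod 1/2, tetrapod 2/3, wave 5/6, as forced by the number of limbs
#' swinging simultaneously (3, 2, 1).
#' @param gait template name.
#' @return duty factor `beta` in (0, 1).
#' @export
gait_duty_factor <- function(gait) {
  switch(match.arg(gait, levels(gait_templates()$template)),
         tripod = 1 / 2, left_tetrapod = 2 / 3, right_tetrapod = 2 / 3,
         wave = 5 / 6)
}

#' Simulate canonical gaits with coupled Hopf-style limit-cycle oscillators
#'
#' Six planar oscillators, one per limb; `x` is the limb position
#' parallel to the body axis and the sign of `y` marks swing (`y < 0`)
#' versus stance (`y > 0`). Uneven duty ratios come from the
#' state-dependent frequency
#' `omega = omega_stance + (omega_swing - omega_stance) / (1 + exp(a y))`
#' with `omega_stance = ((1 - beta) / beta) * omega_swing`, so each
#' limb spends the fraction `beta` of its cycle in stance. Each
#' oscillator relaxes to a circular limit cycle of radius `sqrt(mu)`;
#' diffusive rotation-style coupling pulls every pair toward its
#' template-specified timing offset (the rotation angle is duty-factor
#' warped so that gaits with `beta != 1/2` lock to canonical timing
#' rather than to plane-angle offsets; the exactly phased orbit is then
#' an equilibrium of the coupled system). The limb ordering of the
#' realized wave is checked post hoc and relabelled if the
#' time-reversal-symmetric solution emerged, enforcing
#' posterior-to-anterior propagation.
#'
#' White Gaussian noise at the configured signal-to-noise ratio
#' (signal power / noise power, default 12.5) is added to the rendered
#' limb traces; the returned phases are noiseless ground truth.
#'
#' @param gait canonical gait name (see [gait_templates()]).
#' @param duration_s output duration, s (after the transient).
#' @param seed RNG seed (swing-duration draw, initial jitter, noise).
#' @param stepping_freq_hz stepping frequency; `NULL` draws a swing
#'   duration corresponding to a tripod stepping frequency uniform in
#'   `[5, 12.5]` Hz.
#' @param snr signal-to-noise power ratio for the additive trace noise;
#'   `Inf` for noiseless output.
#' @param alpha_self self-interaction strength (1/s).
#' @param mu limit-cycle parameter; limb amplitude is `sqrt(mu)` mm.
#' @param a_sig sigmoid steepness of the swing/stance frequency switch.
#' @param kc coupling strength (1/s).
#' @param transient_s discarded initial interval, s.
#' @param frame_rate output sampling rate, frames/s.
#' @param init `"template"` (on-cycle at template phases plus small
#'   jitter) or `"random"`.
#' @param lock_tol minimum template coherence of the noiseless uniform
#'   phases over the final 20% of the record; failure to reach it is an
#'   error.
#' @return list of class `canonical_gait_sim`: `limbs` (limb table with
#'   noise, incl. camera-frame columns), `phase` (noiseless uniform
#'   phases, cycles, plus `freq_hz`), `params`.
#' @export
simulate_canonical_gait <- function(gait = "tripod", duration_s = 5, seed = 1,
                                    stepping_freq_hz = NULL, snr = 12.5,
                                    alpha_self = 50, mu = 1, a_sig = 2000, kc = 10,
                                    transient_s = 2, frame_rate = 150,
                                    init = c("template", "random"),
                                    lock_tol = 0.99) {
  gait <- match.arg(gait, levels(gait_templates()$template))
  init <- match.arg(init)
  beta <- gait_duty_factor(gait)
  tmpl <- gait_templates() |> dplyr::filter(.data$template == gait)
  psi <- tmpl$psi[match(LIMBS, tmpl$limb)]

  rng_seed <- derive_seed(seed, "canonical")
  sim <- withr::with_seed(rng_seed, {
    # swing duration drawn as for a tripod gait stepping at 5-12.5 Hz
    if (is.null(stepping_freq_hz)) {
      f_trip <- stats::runif(1, 5, 12.5)
      tau_swing <- 1 / (2 * f_trip)
    } else {
      tau_swing <- (1 - beta) / stepping_freq_hz
    }
    omega_swing <- pi / tau_swing
    omega_stance <- (1 - beta) / beta * omega_swing
    A <- sqrt(mu)

    if (init == "template") {
      # exactly on the canonical orbit (a common random cycle offset
      # only); the coupled system holds this solution invariant
      th0 <- warp_uniform_to_angle(psi + stats::runif(1), beta)
    } else {
      th0 <- stats::runif(6, 0, 2 * pi)
    }
    state <- c(A * cos(th0 + pi), A * sin(th0 + pi)) # plane angle = limb angle + pi

    derivs <- function(t, s, p) {
      x <- s[1:6]; y <- s[7:12]
      r2 <- x^2 + y^2
      omega <- omega_stance + (omega_swing - omega_stance) / (1 + exp(a_sig * y))
      dx <- alpha_self * (mu - r2) * x - omega * y
      dy <- alpha_self * (mu - r2) * y + omega * x
      phi <- (atan2(y, x) - pi) # limb angle (rad)
      u <- warp_angle_to_uniform(phi, beta)
      for (j in 1:6) {
        # rotate oscillator j onto every limb's template-implied timing;
        # the j = i term vanishes identically
        delta <- warp_uniform_to_angle(u[j] + psi - psi[j], beta) - phi[j]
        cs <- cos(delta); sn <- sin(delta)
        dx <- dx + kc / 5 * (cs * x[j] - sn * y[j] - x)
        dy <- dy + kc / 5 * (sn * x[j] + cs * y[j] - y)
      }
      list(c(dx, dy))
    }

    times <- seq(0, transient_s + duration_s, by = 1 / frame_rate)
    sol <- deSolve::ode(y = state, times = times, func = derivs, parms = NULL,
                        method = "ode45", rtol = 1e-8, atol = 1e-8)
    list(sol = sol, tau_swing = tau_swing, A = A)
  })

  sol <- sim$sol
  keep <- sol[, 1] > transient_s - 1e-9
  x <- sol[keep, 2:7, drop = FALSE]
  y <- sol[keep, 8:13, drop = FALSE]
  n <- nrow(x)
  # continuous limb angle and uniform phase per limb
  ang <- sapply(1:6, function(i) signal::unwrap(atan2(y[, i], x[, i]) - pi))
  ncyc <- floor(ang / (2 * pi))
  w <- ang %% (2 * pi)
  u_wrapped <- sapply(1:6, function(i) warp_angle_to_uniform(w[, i], beta))
  u_cont <- ncyc + u_wrapped

  period_s <- sim$tau_swing / (1 - beta)
  phase_tbl <- tibble::tibble(
    frame = rep(seq_len(n), times = 6),
    limb = rep(LIMBS, each = n),
    phase = as.vector(u_wrapped) %% 1,
    freq_hz = 1 / period_s,
    swing = as.integer((as.vector(u_wrapped) %% 1) < 1 - beta)
  ) |> dplyr::arrange(.data$frame, .data$limb)

  # post-hoc ordering check: ipsilateral swing onsets must propagate
  # posterior-to-anterior (hind leads mid leads fore)
  relabel <- FALSE
  if (gait %in% c("wave", "left_tetrapod", "right_tetrapod")) {
    lag_mid_hind <- circ_mean((u_cont[, 2] - u_cont[, 3]) %% 1)
    want <- (psi[2] - psi[3]) %% 1
    if (abs(circ_dist(lag_mid_hind, want)) > 0.25) relabel <- TRUE
  }
  if (relabel) {
    remap <- c(L1 = "L3", L2 = "L2", L3 = "L1", R1 = "R3", R2 = "R2", R3 = "R1")
    phase_tbl$limb <- unname(remap[phase_tbl$limb])
    reord <- match(c("L3", "L2", "L1", "R3", "R2", "R1"), LIMBS)
    u_cont <- u_cont[, reord]
    x <- x[, reord]
    phase_tbl <- dplyr::arrange(phase_tbl, .data$frame, .data$limb)
  }

  coh_check <- template_coherence(phase_tbl, gait)
  tail_r <- coh_check$r[coh_check$frame > n * 0.8]
  if (min(tail_r, na.rm = TRUE) < lock_tol) {
    stop(sprintf(
      "failed to phase-lock to the %s template: min tail coherence %.3f < %.2f",
      gait, min(tail_r, na.rm = TRUE), lock_tol), call. = FALSE)
  }

  ap_rest <- c(L1 = 1.5, L2 = 0, L3 = -1.5, R1 = 1.5, R2 = 0, R3 = -1.5)
  lat_rest <- c(L1 = 1, L2 = 1.2, L3 = 1, R1 = -1, R2 = -1.2, R3 = -1)
  stride <- 2 * sim$A
  p_lin <- pmin(u_cont %% 1, 1 - beta) / (1 - beta)
  progress <- swing_progress(p_lin * pi)
  limb_lab <- rep(LIMBS, each = n)
  limbs <- tibble::tibble(
    frame = rep(seq_len(n), times = 6),
    limb = limb_lab,
    x_par = as.vector(x) + ap_rest[limb_lab],
    x_perp = lat_rest[limb_lab],
    x_cam = stride * as.vector(floor(u_cont) + progress) + ap_rest[limb_lab],
    y_cam = lat_rest[limb_lab]
  )
  if (is.finite(snr)) {
    sd_noise <- stats::sd(as.vector(x)) / sqrt(snr)
    limbs <- withr::with_seed(rng_seed + 7L, {
      limbs |> dplyr::mutate(dplyr::across(
        c("x_par", "x_perp", "x_cam", "y_cam"),
        function(v) v + stats::rnorm(length(v), sd = sd_noise)
      ))
    })
  }
  limbs <- dplyr::arrange(limbs, .data$frame, .data$limb)

  structure(list(
    limbs = limbs, phase = phase_tbl,
    params = list(gait = gait, beta = beta, tau_swing_s = sim$tau_swing,
                  stepping_freq_hz = 1 / period_s, snr = snr,
                  snr_convention = "signal power / noise power",
                  alpha_self = alpha_self, mu = mu, a_sig = a_sig, kc = kc,
                  seed = seed, frame_rate = frame_rate, relabelled = relabel)
  ), class = "canonical_gait_sim")
}

#' @method print canonical_gait_sim
#' @export
print.canonical_gait_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("Canonical %s gait: %.1f Hz stepping, beta = %.2f, SNR = %s\n",
              p$gait, p$stepping_freq_hz, p$beta, format(p$snr)))
  invisible(x)
}
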