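test_that("stance-frequency identity holds across duty factors", {
  # omega_stance = ((1 - beta)/beta) * omega_swing, so a limb spends the
  # fraction beta of its cycle in stance
  for (beta in c(0.2, 0.5, 2 / 3, 5 / 6, 0.9)) {
    omega_swing <- pi / 0.05
    omega_stance <- (1 - beta) / beta * omega_swing
    t_swing <- pi / omega_swing
    t_stance <- pi / omega_stance
    expect_equal(t_stance / (t_swing + t_stance), beta, tolerance = 1e-12)
  }
  expect_equal(gait_duty_factor("tripod"), 0.5)
  expect_equal(gait_duty_factor("wave"), 5 / 6)
})

test_that("equal swing and stance durations produce exact alternating tripods", {
  m <- tripod_model()
  w <- phase_wide(model_phase(m))
  # the two tripods are in antiphase
  for (p in list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"))) {
    expect_lt(abs(circ_dist(circ_mean((w[[p[1]]] - w[[p[2]]]) %% 1), 0.5)), 0.01)
  }
  expect_lt(abs(circ_dist(circ_mean((w$L3 - w$L1) %% 1), 0)), 0.01)
  # feet-down count constant at 3
  fd <- model_raster(m) |>
    dplyr::group_by(frame) |>
    dplyr::summarise(fd = sum(1 - swing))
  expect_true(all(fd$fd == 3))
})

test_that("contralateral antiphase holds across the stance-duration range", {
  for (ts in c(40, 120, 210)) {
    m <- simulate_six_limb_model(tau_stance = ts, duration_s = 3,
                                 transient_s = 10, seed = 4)
    w <- phase_wide(model_phase(m))
    for (p in list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"))) {
      dm <- circ_mean((w[[p[1]]] - w[[p[2]]]) %% 1)
      expect_lt(abs(circ_dist(dm, 0.5)), 0.01)
    }
  }
})

test_that("hindlimb phase advance matches the stated swing and stance rates", {
  # posterior limbs free-run: phase steps are dt*pi/tau in each regime
  # (negligible cross-body coupling isolates the single-side rules)
  m <- simulate_rule_based(tau_stance = 80, duration_s = 2, transient_s = 1,
                           frame_rate = 150, seed = 2, alpha = 1e-9)
  th <- m$theta[m$limb == "L3"]
  sw <- m$swing[m$limb == "L3"]
  dth <- diff(th)
  # output frames fall on whole integration steps: 267 steps of 0.025 ms
  frame_ms <- round(1000 / 150 / 0.025) * 0.025
  # interior frames fully inside one regime advance at exactly pi/tau
  inside_sw <- which(sw[-length(sw)] == 1 & sw[-1] == 1)
  inside_st <- which(sw[-length(sw)] == 0 & sw[-1] == 0)
  # regime switches can occur within a frame; use medians
  expect_equal(stats::median(dth[inside_sw]), frame_ms * pi / 40, tolerance = 1e-6)
  expect_equal(stats::median(dth[inside_st]), frame_ms * pi / 80, tolerance = 1e-6)
})

test_that("a midlimb swing is slowed while its posterior neighbour swings", {
  m <- simulate_rule_based(tau_stance = 120, duration_s = 3, transient_s = 10,
                           seed = 6)
  th2 <- m$theta[m$limb == "L2"]
  sw2 <- m$swing[m$limb == "L2"]
  sw3 <- m$swing[m$limb == "L3"]
  dth <- diff(th2)
  frame_ms <- 1000 / 150
  both <- which(sw2[-length(sw2)] == 1 & sw2[-1] == 1 &
                  sw3[-length(sw3)] == 1 & sw3[-1] == 1)
  alone <- which(sw2[-length(sw2)] == 1 & sw2[-1] == 1 &
                   sw3[-length(sw3)] == 0 & sw3[-1] == 0)
  if (length(both) > 3 && length(alone) > 3) {
    # rate halved while the posterior neighbour is also in swing
    expect_equal(stats::median(dth[both]) / stats::median(dth[alone]), 0.5,
                 tolerance = 0.05)
  } else {
    succeed("no overlapping swing frames at this setting")
  }
})

test_that("Euler (rule-based) and Heun trajectories agree at the reference timestep", {
  th0 <- c(0.3, 2.1, 4.4, 3.4, 5.2, 1.2)
  he <- simulate_six_limb_model(tau_stance = 80, duration_s = 2, transient_s = 0,
                                theta0 = th0, dt = 0.025)
  eu <- simulate_rule_based(tau_stance = 80, duration_s = 2, transient_s = 0,
                            theta0 = th0, dt = 0.025)
  rms <- sqrt(mean((he$theta - eu$theta)^2))
  expect_lt(rms, 1e-2)
})

test_that("halving the timestep barely changes Heun trajectories", {
  th0 <- c(0.3, 2.1, 4.4, 3.4, 5.2, 1.2)
  # frame rate 160 makes the output grids of both timesteps coincide
  # (6.25 ms = 250 or 500 whole steps)
  a <- simulate_six_limb_model(tau_stance = 100, duration_s = 5, transient_s = 0,
                               theta0 = th0, dt = 0.025, frame_rate = 160)
  b <- simulate_six_limb_model(tau_stance = 100, duration_s = 5, transient_s = 0,
                               theta0 = th0, dt = 0.0125, frame_rate = 160)
  # the indicator discontinuities limit convergence to first order at
  # switching events, so agreement is good but not spectral
  expect_lt(sqrt(mean((a$theta - b$theta)^2)), 5e-3)
})

test_that("the integrator rejects unstable timesteps", {
  expect_error(simulate_six_limb_model(tau_stance = 40, dt = 5), "dt too large")
})

test_that("cross-body coupling strength does not qualitatively change the pattern", {
  for (al in c(1 / 8, 1 / 2)) {
    m <- simulate_six_limb_model(tau_stance = 120, alpha = al, duration_s = 3,
                                 transient_s = 10, seed = 9)
    w <- phase_wide(model_phase(m))
    expect_lt(abs(circ_dist(circ_mean((w$L2 - w$R2) %% 1), 0.5)), 0.01)
    # posterior-to-anterior metachronal order is preserved: the hindlimb
    # leads its ipsilateral midlimb by a fraction of a half-cycle
    hm <- circ_mean((w$L3 - w$L2) %% 1)
    expect_gt(hm, 0.02)
    expect_lt(hm, 0.5)
  }
})

test_that("uncoupled Hopf oscillator relaxes to the limit-cycle radius", {
  # single oscillator: kc = 0, start off-cycle
  mu <- 1.44
  derivs <- function(t, s, p) {
    r2 <- s[1]^2 + s[2]^2
    list(c(50 * (mu - r2) * s[1] - 60 * s[2],
           50 * (mu - r2) * s[2] + 60 * s[1]))
  }
  sol <- deSolve::ode(c(0.2, 0), times = seq(0, 2, 0.01), derivs, NULL)
  r_end <- unname(sqrt(sol[nrow(sol), 2]^2 + sol[nrow(sol), 3]^2))
  expect_equal(r_end, sqrt(mu), tolerance = 1e-6)
})

test_that("canonical simulator locks to each template", {
  for (fx in list(tripod_sim(), tetrapod_sim(), wave_sim())) {
    g <- fx$params$gait
    co <- template_coherence(fx$phase, g)
    tail_r <- co$r[co$frame > max(co$frame) * 0.5]
    expect_gt(min(tail_r), 0.99)
  }
})

test_that("noise at SNR 12.5 lowers coherence but preserves the template argmax", {
  s <- simulate_canonical_gait("tripod", duration_s = 3, seed = 5, snr = 12.5)
  ph <- estimate_phase(s$limbs)
  bf <- best_gait_fraction(ph)
  frac <- bf$summary$fraction[bf$summary$template == "tripod"]
  expect_gt(frac, 0.9)
  mean_r <- bf$summary$mean_r[bf$summary$template == "tripod"]
  expect_lt(mean_r, 0.999)
  expect_gt(mean_r, 0.8)
  # the realized noise follows the power-ratio convention
  clean <- simulate_canonical_gait("tripod", duration_s = 3, seed = 5, snr = Inf)
  noise <- s$limbs$x_par - clean$limbs$x_par
  x <- clean$limbs$x_par - ave(clean$limbs$x_par, clean$limbs$limb)
  expect_equal(stats::var(x) / stats::var(noise), 12.5, tolerance = 0.15)
})

test_that("simulator stepping frequencies span the stated tripod range", {
  f <- vapply(1:12, function(s) {
    simulate_canonical_gait("tripod", duration_s = 0.5, seed = s,
                            transient_s = 0.5)$params$stepping_freq_hz
  }, numeric(1))
  expect_true(all(f >= 5 & f <= 12.5))
  expect_gt(max(f) - min(f), 2) # the draw actually varies
})

test_that("relative-phase trends across the sweep match the continuum picture", {
  taus <- c(40, 80, 150, 210)
  stats_by_tau <- purrr::map_dfr(taus, function(ts) {
    m <- simulate_six_limb_model(tau_stance = ts, duration_s = 3,
                                 transient_s = 10, seed = 12)
    w <- phase_wide(model_phase(m))
    hm <- circ_mean((w$L3 - w$L2) %% 1) # hind-mid
    hf <- circ_mean((w$L3 - w$L1) %% 1) # hind-fore
    sd_all <- mean(c(circ_sd((w$L1 - w$R1) %% 1), circ_sd((w$L3 - w$L2) %% 1),
                     circ_sd((w$L3 - w$L1) %% 1)))
    tibble::tibble(tau = ts, hm = hm, hf = hf, sd_all = sd_all)
  })
  # ipsilateral pairs approach antiphase (hind-mid) / in-phase (hind-fore)
  # as stance shortens (stepping frequency increases)
  d_hm <- abs(circ_dist(stats_by_tau$hm, 0.5))
  expect_true(all(diff(d_hm) > -1e-9)) # deviation grows with tau
  d_hf <- abs(circ_dist(stats_by_tau$hf, 0))
  expect_lt(d_hf[1], 0.01)
  expect_gt(d_hf[4], d_hf[1])
  # spread of relative phases decreases with stepping frequency
  expect_true(all(diff(stats_by_tau$sd_all) > -1e-9))
})
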