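# Shared fixtures, built once per test run. Everything is generated in
# code; no data files.

fixture_env <- new.env(parent = emptyenv())

# memoise expensive simulations across test files
fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

tripod_model <- function() {
  fixture("tripod_model", function() {
    simulate_six_limb_model(tau_stance = 40, duration_s = 3, transient_s = 5,
                            seed = 11)
  })
}

mid_model <- function() {
  fixture("mid_model", function() {
    simulate_six_limb_model(tau_stance = 60, duration_s = 4, transient_s = 10,
                            seed = 11)
  })
}

slow_model <- function() {
  fixture("slow_model", function() {
    simulate_six_limb_model(tau_stance = 100, duration_s = 4, transient_s = 10,
                            seed = 11)
  })
}

tripod_sim <- function() {
  fixture("tripod_sim", function() {
    simulate_canonical_gait("tripod", duration_s = 3, seed = 5, snr = Inf)
  })
}

wave_sim <- function() {
  fixture("wave_sim", function() {
    simulate_canonical_gait("wave", duration_s = 3, seed = 5, snr = Inf)
  })
}

tetrapod_sim <- function() {
  fixture("tetrapod_sim", function() {
    simulate_canonical_gait("left_tetrapod", duration_s = 3, seed = 5, snr = Inf)
  })
}

const_body <- function(n, v_par = 15, v_rot = 0) {
  tibble::tibble(frame = seq_len(n), v_par = v_par, v_perp = 0, v_rot = v_rot)
}

# wide phase table helper
phase_wide <- function(phase) {
  tidyr::pivot_wider(phase[, c("frame", "limb", "phase")],
                     names_from = "limb", values_from = "phase")
}

# six-limb phase table at fixed per-limb phases (single frame or n frames)
phase_table <- function(phases, n = 1) {
  tibble::tibble(
    frame = rep(seq_len(n), times = 6),
    limb = rep(hexgait::LIMBS, each = n),
    phase = rep(phases, each = n),
    freq_hz = 10
  )
}

turning_scenario <- function() {
  fixture("turning_scenario", function() {
    synth_behavior_generator(list(
      duration_s = 15, tau_stance = 55,
      turns = list(n = 4, peak_yaw = 300, width_ms = 300,
                   modulation = list(stance_dur = c(I2 = 0.2, I3 = 0.3,
                                                    O2 = -0.1, O3 = -0.1)))
    ), seed = 2)
  })
}

perturbation_scenario <- function() {
  fixture("perturbation_scenario", function() {
    synth_behavior_generator(list(
      duration_s = 15, tau_stance = 60,
      perturbations = list(times_s = c(4, 8, 12), tau_stance_new = 90,
                           hold_ms = 400)
    ), seed = 3)
  })
}
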