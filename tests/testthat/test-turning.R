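test_that("yaw extrema detection finds analytic and imposed peaks", {
  # constant yaw: nothing to find
  body <- const_body(200, v_rot = 50)
  expect_identical(nrow(detect_yaw_extrema(body)), 0L)

  # sinusoidal yaw: two extrema per period, alternating sides
  n <- 600
  body <- tibble::tibble(frame = 1:n, v_par = 15, v_perp = 0,
                         v_rot = 300 * sin(2 * pi * (1:n) / 150))
  ev <- detect_yaw_extrema(body, min_prominence = 100)
  expect_identical(nrow(ev), 8L) # 4 periods x 2 extrema
  expect_identical(as.character(ev$side), rep(c("left", "right"), 4))

  # scenario with K imposed turn pulses: exactly K events
  sc <- turning_scenario()
  ev2 <- detect_yaw_extrema(sc$body)
  expect_identical(nrow(ev2), 4L)
  imposed <- sc$events$frame[sc$events$type == "turn"]
  expect_true(all(abs(sort(ev2$frame) - sort(imposed)) <= 2))
})

test_that("turning modulation curves recover imposed per-limb gains", {
  sc <- turning_scenario()
  steps <- extract_steps(sc$limbs, sc$truth$raster, sc$body)
  steps$video <- rep(1:4, length.out = nrow(steps))
  mc <- turning_modulation_curves(steps, speed_band = c(5, 30),
                                  yaw_breaks = seq(0, 320, by = 80),
                                  n_resamples = 200, seed = 1)
  top <- mc[mc$parameter == "stance_dur_ms" & mc$yaw_bin_center == 280, ]
  # imposed at peak yaw: inside mid +20%, inside hind +30%, outside
  # mid/hind -10%; steps in the top bin sit slightly below peak yaw
  i3 <- top[top$limb_role == "I3", ]
  expect_gt(i3$modulation, 20)
  expect_lt(i3$modulation, 35)
  expect_true(i3$ci_lo <= 30 * 0.95 && 30 * 0.75 <= i3$ci_hi)
  i2 <- top[top$limb_role == "I2", ]
  expect_gt(i2$modulation, 12)
  expect_lt(i2$modulation, 25)
  o3 <- top[top$limb_role == "O3", ]
  expect_lt(o3$modulation, -3)
  expect_gt(o3$modulation, -16)
  # reference bin is zero by construction
  expect_true(all(mc$modulation[mc$yaw_bin_center == 40] == 0, na.rm = TRUE))
})

test_that("a symmetric scenario yields flat modulation curves", {
  sc <- fixture("null_scenario2", function() {
    synth_behavior_generator(list(
      duration_s = 15, tau_stance = 55,
      turns = list(n = 4, peak_yaw = 300, width_ms = 300, modulation = list())
    ), seed = 5)
  })
  expect_true(all(sc$truth$sched_stance == 1))
  steps <- extract_steps(sc$limbs, sc$truth$raster, sc$body)
  mc <- turning_modulation_curves(steps, speed_band = c(5, 30),
                                  yaw_breaks = seq(0, 320, by = 80),
                                  n_resamples = 0)
  durs <- mc[mc$parameter %in% c("stance_dur_ms", "swing_dur_ms") & mc$n > 0, ]
  expect_true(all(abs(durs$modulation) < 8)) # frame quantization of durations
})

test_that("mirroring the dataset leaves symmetrized curves unchanged", {
  sc <- turning_scenario()
  steps <- extract_steps(sc$limbs, sc$truth$raster, sc$body)
  mirror <- steps
  swap <- c(L1 = "R1", L2 = "R2", L3 = "R3", R1 = "L1", R2 = "L2", R3 = "L3")
  mirror$limb <- unname(swap[mirror$limb])
  mirror$yaw_mean <- -mirror$yaw_mean
  mirror$step_dir_deg <- -mirror$step_dir_deg
  a <- turning_modulation_curves(steps, speed_band = c(5, 30),
                                 yaw_breaks = seq(0, 320, by = 80),
                                 n_resamples = 0)
  b <- turning_modulation_curves(mirror, speed_band = c(5, 30),
                                 yaw_breaks = seq(0, 320, by = 80),
                                 n_resamples = 0)
  expect_equal(a$modulation, b$modulation, tolerance = 1e-9)
})

test_that("phase distributions at extrema detect phase-locked turns", {
  sc <- fixture("locked_scenario", function() {
    synth_behavior_generator(list(
      duration_s = 30, tau_stance = 55,
      turns = list(n = 12, peak_yaw = 300, width_ms = 200, alternate = FALSE,
                   phase_lock = list(limb = "L2", phase = 0.25),
                   modulation = list())
    ), seed = 6)
  })
  ev <- detect_yaw_extrema(sc$body)
  expect_gte(nrow(ev), 10)
  ph <- sc$truth$phase
  pd <- phase_distribution_at_extrema(ph, ev, n_perm = 500, seed = 2)
  # all turns are leftward, so the inside midlimb role is always L2 and
  # its event-phase density peaks at the locked phase
  dens <- pd$densities[pd$densities$limb_role == "I2" &
                         pd$densities$source == "extrema", ]
  pk <- dens$phase[which.max(dens$density)]
  expect_lt(abs(circ_dist(pk, 0.25)), 0.1)
  mid_tests <- pd$tests[pd$tests$limb_role %in% c("I2", "O2"), ]
  expect_true(all(mid_tests$p.value < 0.05))
})

test_that("uniformly drawn events are indistinguishable from the all-frame distribution", {
  m <- slow_model()
  ph <- model_phase(m)
  nmax <- max(ph$frame)
  withr::with_seed(3, {
    ev <- tibble::tibble(frame = sample(5:(nmax - 5), 60),
                         side = sample(c("left", "right"), 60, replace = TRUE))
  })
  pd <- phase_distribution_at_extrema(ph, ev, n_perm = 400, seed = 1)
  expect_true(all(pd$tests$p.value > 0.05))
})

test_that("stance phases dominate the time-invariant distribution when stance is longer", {
  m <- slow_model() # tau_stance = 100 > tau_swing = 40
  ph <- model_phase(m)
  # phases in [0.5, 1) correspond to stance and should carry more mass
  frac_stance <- mean(ph$phase >= 0.5)
  expect_gt(frac_stance, 0.6)
})

test_that("too few events skips the tests with notice", {
  m <- tripod_model()
  ph <- model_phase(m)
  ev <- tibble::tibble(frame = c(50, 80), side = c("left", "right"))
  pd <- phase_distribution_at_extrema(ph, ev, min_events = 10)
  expect_true(pd$skipped)
  expect_true(all(is.na(pd$tests$p.value)))
})
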