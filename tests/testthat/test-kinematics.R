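test_that("zero-phase Gaussian smoothing preserves constants and attenuates per the closed form", {
  n <- 600
  body <- tibble::tibble(frame = 1:n, v_par = 5, v_perp = 0, v_rot = 0)
  sm <- smooth_body_velocities(body, sigma_ms = 20)
  expect_equal(sm$v_par, rep(5, n), tolerance = 1e-10)
  expect_true(isTRUE(attr(sm, "smoothed")))

  # sinusoid at 10 Hz: attenuation of the forward-backward pass follows
  # |H(f)| = exp(-(2 pi f sigma)^2)
  f <- 10
  t <- (0:(n - 1)) / 150
  body$v_par <- sin(2 * pi * f * t)
  sm <- smooth_body_velocities(body, sigma_ms = 20)
  mid <- 100:500
  gain <- sd(sm$v_par[mid]) / sd(body$v_par[mid])
  expect_equal(gain, exp(-(2 * pi * f * 0.020)^2), tolerance = 0.01)

  # impulse: kernel weights sum to one
  body$v_par <- c(rep(0, 300), 1, rep(0, n - 301))
  sm <- smooth_body_velocities(body, sigma_ms = 20)
  expect_equal(sum(sm$v_par), 1, tolerance = 1e-9)
})

test_that("swing/stance classification thresholds limb speed", {
  n <- 100
  still <- tidyr::crossing(frame = 1:n, limb = LIMBS) |>
    dplyr::mutate(x_par = 1, x_perp = 2, x_cam = 3, y_cam = 4)
  r <- classify_swing_stance(still)
  expect_true(all(r$swing == 0)) # motionless limb: all stance

  # steady translation at 30 mm/s exceeds the 20 mm/s threshold
  moving <- tidyr::crossing(frame = 1:n, limb = LIMBS) |>
    dplyr::mutate(x_par = 0, x_perp = 0, x_cam = 30 * (frame / 150), y_cam = 0)
  r <- classify_swing_stance(moving)
  expect_true(all(r$swing == 1))
  # ... but not a 10 mm/s drift
  slow <- dplyr::mutate(moving, x_cam = 10 * (frame / 150))
  expect_true(all(classify_swing_stance(slow)$swing == 0))
})

test_that("classification is monotone in the threshold", {
  lt <- render_limb_positions(tripod_model())
  r1 <- classify_swing_stance(lt, speed_threshold = 10)
  r2 <- classify_swing_stance(lt, speed_threshold = 20)
  r3 <- classify_swing_stance(lt, speed_threshold = 40)
  # raising the threshold never converts stance to swing
  expect_true(all(r2$swing <= r1$swing))
  expect_true(all(r3$swing <= r2$swing))
})

test_that("rendered tripod model yields duty factor 1/2 and 40 ms phase durations", {
  lt <- render_limb_positions(tripod_model())
  r <- classify_swing_stance(lt)
  duty <- r |>
    dplyr::group_by(limb) |>
    dplyr::summarise(duty = mean(swing == 0))
  expect_true(all(abs(duty$duty - 0.5) <= 0.05))

  body <- const_body(max(lt$frame))
  steps <- extract_steps(lt, r, body)
  expect_gt(nrow(steps), 50)
  expect_true(all(abs(steps$swing_dur_ms - 40) <= 7))
  expect_true(all(abs(steps$stance_dur_ms - 40) <= 7))
})

test_that("step extraction returns an empty table without swing events and exact step lengths on constructed data", {
  n <- 120
  still <- tidyr::crossing(frame = 1:n, limb = LIMBS) |>
    dplyr::mutate(x_par = 0, x_perp = 0, x_cam = 0, y_cam = 0)
  r <- classify_swing_stance(still)
  steps <- extract_steps(still, r, const_body(n))
  expect_identical(nrow(steps), 0L)

  # body advancing at 10 mm/s, feet stationary in stance, period 100 ms:
  # touchdown-to-touchdown displacement = 1 mm
  m <- simulate_six_limb_model(tau_stance = 50, tau_swing = 50, duration_s = 4,
                               transient_s = 5, seed = 3)
  lt <- render_limb_positions(m, amplitude_mm = 0.5) # stride 2A = 1 mm
  r <- model_raster(m) # ground-truth raster
  steps <- extract_steps(lt, r, const_body(max(lt$frame), v_par = 10))
  expect_gt(nrow(steps), 20)
  expect_true(all(abs(stats::na.omit(steps$step_length_mm) - 1) < 1e-6))
})

test_that("stance power law recovers generating parameters and matches the log-log oracle", {
  withr::with_seed(21, {
    v <- runif(300, 2, 30)
    steps <- tibble::tibble(v_par_mean = v,
                            stance_dur_ms = 932.8 * v^(-1.025))
    fit <- fit_stance_power_law(steps)
    expect_equal(fit$a_pl, 932.8, tolerance = 1e-6)
    expect_equal(fit$b, -1.025, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)

    # log-log least squares gives the identical solution on noiseless data
    ols <- lm(log(stance_dur_ms) ~ log(v_par_mean), data = steps)
    expect_equal(exp(coef(ols)[[1]]), fit$a_pl, tolerance = 1e-6)
    expect_equal(coef(ols)[[2]], fit$b, tolerance = 1e-6)

    # constant stance durations: exponent ~ 0
    flat <- tibble::tibble(v_par_mean = v, stance_dur_ms = 80)
    expect_lt(abs(fit_stance_power_law(flat)$b), 1e-6)

    # identical velocities: unidentifiable
    expect_error(fit_stance_power_law(
      tibble::tibble(v_par_mean = rep(10, 10), stance_dur_ms = runif(10, 50, 90))),
      "unidentifiable")
  })
})

test_that("tidy and glance report the power-law fit", {
  withr::with_seed(3, {
    v <- runif(100, 2, 25)
    steps <- tibble::tibble(v_par_mean = v,
                            stance_dur_ms = 932.8 * v^(-1.025) * exp(rnorm(100, 0, 0.1)))
  })
  fit <- fit_stance_power_law(steps)
  td <- tidy(fit)
  expect_setequal(td$term, c("a_pl", "b"))
  gl <- glance(fit)
  expect_true(all(c("r.squared", "a_pl", "b", "nobs") %in% names(gl)))
  expect_lte(gl$r.squared, 1)
})

test_that("canonical rasters have the canonical configuration counts", {
  for (cs in list(c("tripod", 2L), c("left_tetrapod", 3L),
                  c("right_tetrapod", 3L), c("wave", 6L))) {
    cg <- canonical_gait_raster(cs[1], n_cycles = 5, frames_per_cycle = 12)
    s <- stance_config_stats(cg$raster, const_body(max(cg$raster$frame)))
    expect_identical(s$n_configs, as.integer(cs[2]))
  }
  # wave: every configuration has exactly one limb in swing
  cg <- canonical_gait_raster("wave", n_cycles = 5, frames_per_cycle = 12)
  s <- stance_config_stats(cg$raster, const_body(max(cg$raster$frame)))
  expect_true(all(s$per_frame$feet_down == 5))

  # all-stance raster: a single all-down configuration
  allst <- tidyr::crossing(frame = 1:50, limb = LIMBS) |>
    dplyr::mutate(swing = 0L)
  s <- stance_config_stats(allst, const_body(50))
  expect_identical(s$n_configs, 1L)
  expect_identical(unique(s$per_frame$config), "111111")
  expect_true(all(s$per_frame$feet_down == 6))
})

test_that("walking filter excludes slow frames and dwell times split at bout gaps", {
  cg <- canonical_gait_raster("tripod", n_cycles = 4, frames_per_cycle = 12)
  n <- max(cg$raster$frame)
  body <- const_body(n)
  body$v_par[13:24] <- 0.1 # sub-threshold bout in the middle
  s <- stance_config_stats(cg$raster, body)
  expect_identical(nrow(s$per_frame), n - 12L)
  expect_false(any(dplyr::between(s$per_frame$frame, 13, 24)))
})
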