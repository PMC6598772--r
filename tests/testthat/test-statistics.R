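test_that("Clopper-Pearson bounds match the analytic forms", {
  # zero exceedances in 1e5 permutations: upper limit 3.68e-5
  ci <- clopper_pearson(0, 1e5)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 3.68e-5, tolerance = 0.002)
  # exact analytic form at x = 0: 1 - 0.025^(1/n)
  expect_equal(ci$upper, 1 - 0.025^(1 / 1e5), tolerance = 1e-12)
  # symmetry at x = n
  ci1 <- clopper_pearson(50, 50)
  expect_equal(ci1$upper, 1)
  expect_equal(ci1$lower, 0.025^(1 / 50), tolerance = 1e-12)
})

test_that("Kuiper permutation test handles identical and shifted samples", {
  withr::with_seed(2, {
    a <- runif(30)
    kt <- kuiper_mc_test(a, a, n_perm = 500, seed = 1)
    expect_equal(kt$statistic, 0)
    expect_equal(kt$p_value, 1, tolerance = 0.05) # V = 0: every permutation ties
    # strongly separated circular samples
    b <- (rnorm(30, 0, 0.02)) %% 1
    c <- (rnorm(30, 0.5, 0.02)) %% 1
    kt2 <- kuiper_mc_test(b, c, n_perm = 500, seed = 1)
    expect_lt(kt2$p_value, 0.01)
    expect_identical(kt2$x, 0L)
    expect_equal(kt2$p_ci$upper, 1 - 0.025^(1 / 500), tolerance = 1e-9)
  })
})

test_that("permutation p agrees with exhaustive enumeration at n = 4 + 4", {
  a <- c(0.05, 0.12, 0.31, 0.48)
  b <- c(0.52, 0.69, 0.77, 0.93)
  v_obs <- kuiper_statistic(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(8, 4)
  v_all <- apply(combos, 2, function(idx) {
    kuiper_statistic(pooled[idx], pooled[-idx])
  })
  p_exact <- mean(v_all >= v_obs - 1e-12)
  kt <- kuiper_mc_test(a, b, n_perm = 20000, seed = 3)
  expect_equal(kt$p_bound, p_exact, tolerance = 0.02)
})

test_that("permutation p-values are super-uniform under the null", {
  withr::with_seed(17, {
    ps <- vapply(1:60, function(i) {
      kuiper_mc_test(runif(12), runif(12), n_perm = 199, seed = i)$p_value
    }, numeric(1))
    for (q in c(0.1, 0.25, 0.5)) {
      expect_lte(mean(ps <= q), q + 3 * sqrt(q * (1 - q) / 60))
    }
  })
})

test_that("KS wrapper matches the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$statistic, 1)
  withr::with_seed(8, {
    a <- sample(1:20, 10, replace = TRUE)
    b <- sample(5:25, 10, replace = TRUE)
    grid <- sort(unique(c(a, b)))
    d_brute <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(ks_two_sample(a, b)$statistic, d_brute, tolerance = 1e-12)
  })
})

test_that("BCa interval collapses for identical units and matches boot's BCa", {
  d <- tibble::tibble(video = rep(1:6, each = 10), y = rep(7, 60))
  ci <- bca_bootstrap_ci(d, function(x) mean(x$y), unit = "video",
                         n_resamples = 200, seed = 1)
  expect_equal(ci$lower, 7)
  expect_equal(ci$upper, 7)
  expect_equal(ci$statistic, 7)

  # independent oracle: boot::boot.ci on the unit means
  withr::with_seed(5, {
    d2 <- tibble::tibble(video = rep(1:25, each = 4),
                         y = rnorm(100, 10, 3) + rep(rnorm(25, 0, 1), each = 4))
  })
  ci2 <- bca_bootstrap_ci(d2, function(x) mean(x$y), unit = "video",
                          n_resamples = 4000, seed = 2)
  unit_means <- tapply(d2$y, d2$video, mean)
  bo <- boot::boot(unit_means, function(x, i) mean(x[i]), R = 4000)
  bci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  expect_equal(ci2$lower, bci[1], tolerance = 0.05)
  expect_equal(ci2$upper, bci[2], tolerance = 0.05)
})

test_that("BCa interval achieves near-nominal coverage for a Gaussian mean", {
  # Monte-Carlo coverage with 50 units per repeat
  withr::with_seed(99, {
    hits <- vapply(1:400, function(i) {
      d <- tibble::tibble(video = 1:50, y = rnorm(50))
      ci <- bca_bootstrap_ci(d, function(x) mean(x$y), unit = "video",
                             n_resamples = 400, seed = i)
      ci$lower <= 0 && 0 <= ci$upper
    }, logical(1))
  })
  expect_gt(mean(hits), 0.95 - 0.03)
  expect_lte(mean(hits), 1)
})

test_that("event-triggered analysis recovers an imposed stance-duration shift", {
  sc <- perturbation_scenario()
  rast <- classify_swing_stance(sc$limbs)
  body <- smooth_body_velocities(sc$body)
  steps <- extract_steps(sc$limbs, rast, body)
  events <- sc$events$frame[sc$events$type == "perturbation"]
  eta <- event_triggered_analysis(body, steps, events, seed = 4)
  expect_identical(eta$selection$n_selected[1], length(events))
  # stance CDF right-shifted: median first stance longer after events
  pert <- eta$first_stance$stance_dur_ms[eta$first_stance$condition == "perturbation"]
  ctrl <- eta$first_stance$stance_dur_ms[eta$first_stance$condition == "control"]
  expect_gt(median(pert) - median(ctrl), 15)
  expect_lt(eta$ks$p.value, 0.01)
  # normalized speed dips below baseline after the event
  sp <- eta$speed[eta$speed$condition == "perturbation", ]
  expect_lt(min(sp$norm_speed[sp$time_ms > 0]), 0.85)
  expect_equal(mean(sp$norm_speed[sp$time_ms < 0]), 1, tolerance = 0.02)
})

test_that("trial selection applies the stated speed thresholds", {
  # a trial with 100-ms pre-event mean speed of 4 mm/s is excluded
  n <- 600
  body <- tibble::tibble(frame = 1:n, v_par = 4, v_perp = 0, v_rot = 0)
  steps <- tibble::tibble(limb = character(), stance_start = integer(),
                          stance_dur_ms = numeric())
  eta <- suppressWarnings(
    event_triggered_analysis(body, steps, events = 300, control_events = 200,
                             seed = 1))
  expect_identical(eta$selection$n_selected, c(0L, 0L))

  # walking above threshold but dipping below 0.1 mm/s post-event: excluded
  body2 <- body
  body2$v_par <- 8
  body2$v_par[320:325] <- 0.05
  eta2 <- suppressWarnings(
    event_triggered_analysis(body2, steps, events = 300, control_events = 100,
                             seed = 1))
  expect_identical(eta2$selection$n_selected[1], 0L)
  expect_identical(eta2$selection$n_selected[2], 1L)
})

test_that("null scenario yields flat normalized speed and a non-significant KS", {
  sc <- fixture("null_scenario", function() {
    synth_behavior_generator(list(duration_s = 12, tau_stance = 60), seed = 9)
  })
  rast <- classify_swing_stance(sc$limbs)
  body <- smooth_body_velocities(sc$body)
  steps <- extract_steps(sc$limbs, rast, body)
  eta <- event_triggered_analysis(body, steps, events = c(400, 900, 1400),
                                  seed = 2)
  sp <- eta$speed[eta$speed$condition == "perturbation", ]
  expect_true(all(abs(sp$norm_speed - 1) < 0.05))
  expect_gt(eta$ks$p.value, 0.05)
})
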