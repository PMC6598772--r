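#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Resamples grouping units (videos or trajectories) with replacement,
#' computes the statistic on each resample, and forms the BCa interval:
#' the bias correction `z0` comes from the fraction of the bootstrap
#' distribution below the observed statistic, and the acceleration `a`
#' from a jackknife over units.
#'
#' @param data a data frame.
#' @param statistic function mapping a data frame to a scalar.
#' @param unit name of the column identifying resampling units.
#' @param n_resamples number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return one-row tibble of class `bca_ci`: `statistic`, `lower`,
#'   `upper`, `level`, `n_units`, `n_resamples`, `unit`, `n_redrawn`.
#' @export
bca_bootstrap_ci <- function(data, statistic, unit = "video", n_resamples = 1000,
                             level = 0.95, seed = 1) {
  if (!unit %in% names(data)) stop("no column `", unit, "` in data", call. = FALSE)
  ids <- unique(data[[unit]])
  n_units <- length(ids)
  if (n_units < 2) stop("need at least 2 resampling units", call. = FALSE)
  rows_by_unit <- split(seq_len(nrow(data)), data[[unit]])[as.character(ids)]
  theta_hat <- statistic(data)

  boot <- withr::with_seed(derive_seed(seed, "bootstrap"), {
    vals <- numeric(n_resamples)
    redrawn <- 0L
    for (b in seq_len(n_resamples)) {
      repeat {
        pick <- sample(n_units, n_units, replace = TRUE)
        v <- tryCatch(statistic(data[unlist(rows_by_unit[pick]), , drop = FALSE]),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 10L * n_resamples)
          stop("statistic repeatedly undefined on resamples", call. = FALSE)
      }
      vals[b] <- v
    }
    list(vals = vals, redrawn = redrawn)
  })

  # bias correction; clamp to keep z0 finite in degenerate cases
  prop <- (sum(boot$vals < theta_hat) + 0.5 * sum(boot$vals == theta_hat)) / n_resamples
  z0 <- stats::qnorm(min(max(prop, 1 / (2 * n_resamples)), 1 - 1 / (2 * n_resamples)))
  # acceleration from the jackknife over units
  jack <- vapply(seq_len(n_units), function(i) {
    statistic(data[unlist(rows_by_unit[-i]), , drop = FALSE])
  }, numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom < 1e-30) 0 else sum((jm - jack)^3) / (6 * denom)

  alpha <- (1 - level) / 2
  z <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  ci <- stats::quantile(boot$vals, probs = adj, names = FALSE, type = 6)

  structure(tibble::tibble(
    statistic = theta_hat, lower = ci[1], upper = ci[2], level = level,
    n_units = n_units, n_resamples = n_resamples, unit = unit,
    n_redrawn = boot$redrawn
  ), class = c("bca_ci", "tbl_df", "tbl", "data.frame"))
}

#' Exact Clopper-Pearson interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return tibble `estimate`, `lower`, `upper`.
#' @examples
#' clopper_pearson(0, 1e5)$upper # 3.68e-5
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(x >= 0, x <= n)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  tibble::tibble(estimate = x / n, lower = lower, upper = upper)
}

#' Two-sample Monte Carlo permutation test with the Kuiper V statistic
#'
#' Tests whether two circular samples (cycles on `[0, 1)`) come from the
#' same distribution. The observed rotation-invariant Kuiper
#' `V = D+ + D-` is compared against `n_perm` pooled relabelings. The
#' p-value is reported both as the add-one estimate
#' `(x + 1) / (n_perm + 1)` and as the bound `x / n_perm` with an exact
#' Clopper-Pearson interval; with zero exceedances in 1e5 permutations
#' the 95% interval is `[0, 3.68e-5]`.
#'
#' @param a,b circular samples in cycles.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `kuiper_test`: `statistic`, `x` (exceedances),
#'   `n_perm`, `p_value` (add-one), `p_bound`, `p_ci` (tibble), `n_a`,
#'   `n_b`.
#' @export
kuiper_mc_test <- function(a, b, n_perm = 1e5, seed = 1) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  v_obs <- kuiper_statistic(a, b)
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  x <- withr::with_seed(derive_seed(seed, "permutation"), {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      kuiper_statistic(pooled[idx], pooled[-idx])
    }, numeric(1)) >= v_obs - 1e-12)
  })
  structure(list(
    statistic = v_obs, x = x, n_perm = n_perm,
    p_value = (x + 1) / (n_perm + 1),
    p_bound = x / n_perm,
    p_ci = clopper_pearson(x, n_perm),
    n_a = na, n_b = length(b)
  ), class = "kuiper_test")
}

#' @method print kuiper_test
#' @export
print.kuiper_test <- function(x, ...) {
  cat(sprintf(
    "Two-sample Kuiper Monte-Carlo test: V = %.4f, x = %d of %d permutations\n",
    x$statistic, x$x, x$n_perm))
  cat(sprintf("  p (add-one) = %.3g; 95%% CI for p: [%.3g, %.3g]\n",
              x$p_value, x$p_ci$lower, x$p_ci$upper))
  invisible(x)
}

#' @export
tidy.kuiper_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, exceedances = x$x, n_perm = x$n_perm,
                 p.value = x$p_value, p.bound = x$p_bound,
                 p.ci.lower = x$p_ci$lower, p.ci.upper = x$p_ci$upper)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin tidy wrapper around [stats::ks.test()] for real-valued samples.
#' @param a,b numeric samples.
#' @return tibble `statistic` (D), `p.value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  k <- suppressWarnings(stats::ks.test(a, b))
  tibble::tibble(statistic = unname(k$statistic), p.value = k$p.value,
                 n_a = length(a), n_b = length(b))
}

#' Perturbation-triggered speed and stance-duration analysis
#'
#' For each trigger event, trials are selected when the fly walked above
#' `min_pre_speed` (mm/s) on average in the `pre_ms` before the event
#' and its forward velocity never dropped below `min_post_speed` within
#' `post_ms` after it. Forward speed is normalized to the pre-event mean
#' per trial; the first stance duration beginning after the event is
#' pooled over all six limbs and compared against control events
#' (random trigger times under identical selection) with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param body body table with smoothed `v_par`.
#' @param steps step table from [extract_steps()].
#' @param events trigger frames.
#' @param control_events control trigger frames, or `NULL` to draw
#'   `length(events)` random frames uniformly over the valid range,
#'   excluding the analysis window around every real event so controls
#'   never sample perturbation-affected behaviour.
#' @param pre_ms,post_ms selection/normalization windows, ms.
#' @param min_pre_speed,min_post_speed selection thresholds, mm/s.
#' @param frame_rate frames per second.
#' @param seed RNG seed for control draws.
#' @return list of class `event_triggered`: `speed` (condition, time_ms,
#'   mean normalized speed, n), `first_stance` (condition, stance
#'   durations), `ks` (tibble), `selection` (condition, n_events,
#'   n_selected).
#' @export
event_triggered_analysis <- function(body, steps, events, control_events = NULL,
                                     pre_ms = 100, post_ms = 500,
                                     min_pre_speed = 5, min_post_speed = 0.1,
                                     frame_rate = 150, seed = 1) {
  pre_f <- round(pre_ms / 1000 * frame_rate)
  post_f <- round(post_ms / 1000 * frame_rate)
  nb <- max(body$frame)
  if (is.null(control_events)) {
    valid <- (pre_f + 1):(nb - post_f)
    # keep controls clear of every real event's analysis window (plus a
    # post-event margin so the first control stance is unperturbed)
    for (e in events) {
      valid <- valid[valid < e - post_f | valid > e + 2 * post_f]
    }
    if (length(valid) < length(events))
      stop("not enough event-free frames for control triggers", call. = FALSE)
    control_events <- withr::with_seed(
      derive_seed(seed, "permutation") + 13L,
      sample(valid, length(events), replace = FALSE)
    )
  }

  analyse <- function(ev, condition) {
    ev <- ev[ev - pre_f >= 1 & ev + post_f <= nb]
    sel <- vapply(ev, function(e) {
      pre <- body$v_par[body$frame >= e - pre_f & body$frame < e]
      post <- body$v_par[body$frame >= e & body$frame <= e + post_f]
      mean(pre) > min_pre_speed && all(post >= min_post_speed)
    }, logical(1))
    kept <- ev[sel]
    traces <- purrr::map_dfr(kept, function(e) {
      idx <- body$frame >= e - pre_f & body$frame <= e + post_f
      v <- body$v_par[idx]
      base <- mean(body$v_par[body$frame >= e - pre_f & body$frame < e])
      tibble::tibble(event = e,
                     time_ms = (body$frame[idx] - e) * 1000 / frame_rate,
                     norm_speed = v / base)
    })
    speed <- if (nrow(traces) > 0) {
      traces |>
        dplyr::group_by(.data$time_ms) |>
        dplyr::summarise(norm_speed = mean(.data$norm_speed), n = dplyr::n(),
                         .groups = "drop") |>
        dplyr::mutate(condition = condition, .before = 1)
    } else {
      tibble::tibble(condition = character(), time_ms = numeric(),
                     norm_speed = numeric(), n = integer())
    }
    stance <- purrr::map_dfr(kept, function(e) {
      steps |>
        dplyr::filter(.data$stance_start >= e) |>
        dplyr::group_by(.data$limb) |>
        dplyr::slice_min(.data$stance_start, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::transmute(condition = condition, event = e, limb = .data$limb,
                         stance_dur_ms = .data$stance_dur_ms)
    })
    list(speed = speed, stance = stance,
         selection = tibble::tibble(condition = condition, n_events = length(ev),
                                    n_selected = length(kept)))
  }

  evr <- analyse(events, "perturbation")
  ctr <- analyse(control_events, "control")
  if (nrow(evr$selection) > 0 && evr$selection$n_selected == 0)
    warning("no perturbation trials survived selection", call. = FALSE)

  ks <- if (nrow(evr$stance) > 0 && nrow(ctr$stance) > 0) {
    ks_two_sample(evr$stance$stance_dur_ms, ctr$stance$stance_dur_ms)
  } else {
    tibble::tibble(statistic = NA_real_, p.value = NA_real_,
                   n_a = nrow(evr$stance), n_b = nrow(ctr$stance))
  }
  structure(list(
    speed = dplyr::bind_rows(evr$speed, ctr$speed),
    first_stance = dplyr::bind_rows(evr$stance, ctr$stance),
    ks = ks,
    selection = dplyr::bind_rows(evr$selection, ctr$selection)
  ), class = "event_triggered")
}

#' @method print event_triggered
#' @export
print.event_triggered <- function(x, ...) {
  print(x$selection)
  cat(sprintf("First-stance KS: D = %.4f, p = %.3g\n",
              x$ks$statistic, x$ks$p.value))
  invisible(x)
}
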