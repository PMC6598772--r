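#' Detect yaw-rate extrema
#'
#' Local maxima of the absolute (smoothed) yaw velocity whose prominence
#' exceeds a floor, used as temporal anchors of turns. Prominence of a
#' peak is the drop to the highest intervening minimum before a higher
#' peak on either side. The turn side is the sign of the yaw rate at the
#' extremum (positive = left).
#'
#' @param body body table with smoothed `v_rot` (deg/s).
#' @param min_prominence prominence floor, deg/s.
#' @param min_separation_frames minimum spacing between retained events
#'   (the larger peak wins).
#' @return tibble `frame`, `v_rot`, `magnitude`, `side` ("left" or
#'   "right"), `v_par` (if available).
#' @export
detect_yaw_extrema <- function(body, min_prominence = 100,
                               min_separation_frames = 15) {
  x <- abs(body$v_rot)
  n <- length(x)
  if (n < 3) return(empty_turn_events(body))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(empty_turn_events(body))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) > 1) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- logical(0)
    chosen <- integer(0)
    for (i in ord) {
      if (all(abs(i - chosen) >= min_separation_frames)) chosen <- c(chosen, i)
    }
    keep <- sort(chosen)
  }
  out <- tibble::tibble(
    frame = body$frame[keep],
    v_rot = body$v_rot[keep],
    magnitude = x[keep],
    side = ifelse(body$v_rot[keep] > 0, "left", "right")
  )
  if ("v_par" %in% names(body)) out$v_par <- body$v_par[keep]
  out
}

empty_turn_events <- function(body) {
  out <- tibble::tibble(frame = integer(), v_rot = numeric(),
                        magnitude = numeric(), side = character())
  if ("v_par" %in% names(body)) out$v_par <- numeric()
  out
}

peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i
  while (j > 1 && x[j - 1] <= x[i]) {
    j <- j - 1
    left_min <- min(left_min, x[j])
  }
  if (j == 1) left_min <- min(x[1:i])
  right_min <- x[i]
  j <- i
  while (j < n && x[j + 1] <= x[i]) {
    j <- j + 1
    right_min <- min(right_min, x[j])
  }
  if (j == n) right_min <- min(x[i:n])
  x[i] - max(left_min, right_min)
}

# Symmetrize steps by turn direction: fold yaw so positive means turning
# toward the limb side labelled "inside"; right turns mirror limb labels
# and flip step-direction sign.
symmetrize_steps <- function(steps) {
  side <- substr(steps$limb, 1, 1)
  seg <- substr(steps$limb, 2, 2)
  turn_left <- steps$yaw_mean >= 0
  inside <- ifelse(turn_left, side == "L", side == "R")
  steps |>
    dplyr::mutate(
      yaw_sym = abs(.data$yaw_mean),
      limb_role = paste0(ifelse(inside, "I", "O"), seg),
      step_dir_sym = ifelse(turn_left, .data$step_dir_deg, -.data$step_dir_deg)
    )
}

#' Per-limb modulation of step kinematics with turning
#'
#' Pools left and right turns by symmetrizing yaw (limbs relabelled
#' inside/outside of the turn, step directions mirrored for right
#' turns), restricts to a forward-speed band (default 15-20 mm/s, to
#' decouple speed from yaw modulation), bins steps by symmetrized yaw,
#' and reports each kinematic parameter relative to the straight-walking
#' reference bin: percent change for durations and step length,
#' difference in degrees for step direction. Confidence intervals are
#' BCa bootstraps over videos when a `video` column with at least two
#' levels is present.
#'
#' @param steps step table (with `yaw_mean` per step, deg/s).
#' @param speed_band forward-velocity band, mm/s.
#' @param yaw_breaks bin edges for symmetrized yaw, deg/s; the first bin
#'   is the straight-walking reference.
#' @param n_resamples bootstrap resamples (0 disables CIs).
#' @param seed RNG seed.
#' @return tibble of class `modulation_curves`: `limb_role`, `parameter`,
#'   `yaw_bin_center`, `modulation`, `ci_lo`, `ci_hi`, `n`.
#' @export
turning_modulation_curves <- function(steps, speed_band = c(15, 20),
                                      yaw_breaks = seq(0, 400, by = 80),
                                      n_resamples = 200, seed = 1) {
  d <- steps |>
    dplyr::filter(.data$v_par_mean >= speed_band[1],
                  .data$v_par_mean <= speed_band[2],
                  !is.na(.data$yaw_mean)) |>
    symmetrize_steps()
  d <- d[d$yaw_sym < max(yaw_breaks), ]
  if (nrow(d) == 0) stop("no steps in the speed band", call. = FALSE)
  d$yaw_bin <- cut(d$yaw_sym, breaks = yaw_breaks, right = FALSE,
                   include.lowest = TRUE)
  centers <- (yaw_breaks[-1] + yaw_breaks[-length(yaw_breaks)]) / 2
  params <- c(swing_dur_ms = "relative", stance_dur_ms = "relative",
              step_length_mm = "relative", step_dir_deg = "additive")
  has_video <- "video" %in% names(d) && length(unique(d$video)) >= 2

  out <- purrr::map_dfr(names(params), function(pm) {
    mode <- params[[pm]]
    col <- if (pm == "step_dir_deg") "step_dir_sym" else pm
    purrr::map_dfr(sort(unique(d$limb_role)), function(role) {
      dr <- d[d$limb_role == role & is.finite(d[[col]]), ]
      ref <- mean(dr[[col]][as.integer(dr$yaw_bin) == 1], na.rm = TRUE)
      purrr::map_dfr(seq_along(centers), function(bi) {
        db <- dr[as.integer(dr$yaw_bin) == bi, ]
        if (nrow(db) == 0) {
          return(tibble::tibble(limb_role = role, parameter = pm,
                                yaw_bin_center = centers[bi], modulation = NA_real_,
                                ci_lo = NA_real_, ci_hi = NA_real_, n = 0L))
        }
        modfun <- function(x) {
          if (mode == "relative") (mean(x) / ref - 1) * 100 else mean(x) - ref
        }
        m <- modfun(db[[col]])
        if (bi == 1) m <- 0 # reference bin: zero by construction
        ci <- c(NA_real_, NA_real_)
        if (bi > 1 && n_resamples > 0 && has_video &&
            length(unique(db$video)) >= 2) {
          b <- bca_bootstrap_ci(db, function(dd) modfun(dd[[col]]),
                                unit = "video", n_resamples = n_resamples,
                                seed = seed)
          ci <- c(b$lower, b$upper)
        }
        tibble::tibble(limb_role = role, parameter = pm,
                       yaw_bin_center = centers[bi], modulation = m,
                       ci_lo = ci[1], ci_hi = ci[2], n = nrow(db))
      })
    })
  })
  class(out) <- c("modulation_curves", class(out))
  out
}

#' Limb-phase distributions at yaw-rate extrema
#'
#' Compares, per limb, the circular distribution of instantaneous phases
#' at yaw-rate extrema against the time-invariant distribution over all
#' walking frames, with a von Mises KDE for each and a two-sample Kuiper
#' Monte-Carlo permutation test. Limbs are relabelled inside/outside of
#' the turn (I1..I3, O1..O3) using each event's side.
#'
#' @param phase phase table.
#' @param events turn events from [detect_yaw_extrema()].
#' @param n_perm permutations for the Kuiper test.
#' @param min_events fewer events than this skips the tests (densities
#'   are still returned when possible).
#' @param seed RNG seed.
#' @return list of class `phase_at_extrema`: `tests` (limb_role, V,
#'   p.value, p.bound, ci bounds, n_event), `densities` (limb_role,
#'   source, phase, density), `n_events`.
#' @export
phase_distribution_at_extrema <- function(phase, events, n_perm = 2000,
                                          min_events = 10, seed = 1) {
  roles <- c("I1", "I2", "I3", "O1", "O2", "O3")
  ev <- events[, c("frame", "side")]
  ev_phase <- dplyr::inner_join(phase, ev, by = "frame", suffix = c("", "_turn"))
  inside <- (ev_phase$side == "left" & substr(ev_phase$limb, 1, 1) == "L") |
    (ev_phase$side == "right" & substr(ev_phase$limb, 1, 1) == "R")
  ev_phase$limb_role <- paste0(ifelse(inside, "I", "O"), substr(ev_phase$limb, 2, 2))
  # the all-frames reference pools left and right limbs of a segment for
  # both roles (time-invariant distribution is side-symmetric)
  all_by_seg <- split(phase$phase, substr(phase$limb, 2, 2))

  skipped <- nrow(events) < min_events
  tests <- purrr::map_dfr(roles, function(role) {
    pe <- ev_phase$phase[ev_phase$limb_role == role]
    ref <- all_by_seg[[substr(role, 2, 2)]]
    if (skipped || length(pe) == 0) {
      return(tibble::tibble(limb_role = role, statistic = NA_real_,
                            p.value = NA_real_, p.bound = NA_real_,
                            p.ci.lower = NA_real_, p.ci.upper = NA_real_,
                            n_event = length(pe), skipped = TRUE))
    }
    kt <- kuiper_mc_test(pe, ref, n_perm = n_perm, seed = seed)
    dplyr::bind_cols(tibble::tibble(limb_role = role),
                     tidy(kt)[, c("statistic", "p.value", "p.bound",
                                  "p.ci.lower", "p.ci.upper")],
                     tibble::tibble(n_event = length(pe), skipped = FALSE))
  })

  densities <- purrr::map_dfr(roles, function(role) {
    pe <- ev_phase$phase[ev_phase$limb_role == role]
    ref <- all_by_seg[[substr(role, 2, 2)]]
    dplyr::bind_rows(
      if (length(pe) >= 5)
        dplyr::mutate(circ_kde(pe), limb_role = role, source = "extrema"),
      dplyr::mutate(circ_kde(ref), limb_role = role, source = "all_frames")
    )
  })

  structure(list(tests = tests, densities = densities, n_events = nrow(events),
                 skipped = skipped),
            class = "phase_at_extrema")
}

#' @method print phase_at_extrema
#' @export
print.phase_at_extrema <- function(x, ...) {
  cat("Phase distributions at", x$n_events, "yaw-rate extrema\n")
  print(x$tests)
  invisible(x)
}
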