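#' Exact canonical-gait rasters and phases
#'
#' Builds the idealized swing/stance raster (and matching uniform
#' phases) of a canonical gait directly from its phase template and duty
#' factor, with each limb swinging for the fraction `1 - beta` of the
#' cycle starting at its template phase. Useful as an analytic oracle:
#' a tripod raster has exactly 2 distinct stance configurations, a
#' tetrapod 3, and a wave 6.
#'
#' With `jitter_frames > 0` every swing onset is shifted by a uniform
#' integer in `[-jitter_frames, jitter_frames]` (swing length kept),
#' emulating the step-timing deviations of real walking; a perfect wave
#' gait keeps exactly five feet down at all times, so it is these
#' deviations that expose the gait's six transitions per cycle in the
#' feet-down count.
#'
#' @param gait canonical gait name.
#' @param n_cycles number of full cycles.
#' @param frames_per_cycle frames per cycle (sets the implied stepping
#'   frequency at a given frame rate).
#' @param frame_rate frames per second (metadata only).
#' @param jitter_frames step-timing jitter amplitude, frames.
#' @param seed RNG seed for the jitter.
#' @return list with `raster` (`frame`, `limb`, `swing`) and `phase`
#'   (`frame`, `limb`, `phase`, `freq_hz`, `swing`).
#' @export
canonical_gait_raster <- function(gait = "tripod", n_cycles = 10,
                                  frames_per_cycle = 12, frame_rate = 150,
                                  jitter_frames = 0, seed = 1) {
  gait <- match.arg(gait, levels(gait_templates()$template))
  beta <- gait_duty_factor(gait)
  if (frames_per_cycle %% 6 != 0)
    stop("frames_per_cycle must be a multiple of 6 so template offsets land on frames",
         call. = FALSE)
  tmpl <- gait_templates() |> dplyr::filter(.data$template == gait)
  psi <- tmpl$psi[match(LIMBS, tmpl$limb)]
  n <- n_cycles * frames_per_cycle
  # integer frame grid: template offsets and the swing window are whole
  # numbers of frames, so swing/stance boundaries are exact
  k_off <- round(psi * frames_per_cycle)
  k_swing <- round((1 - beta) * frames_per_cycle)
  fidx <- as.vector(outer(seq_len(n) - 1L, k_off, "+")) %% frames_per_cycle
  phase <- tibble::tibble(
    frame = rep(seq_len(n), times = 6),
    limb = rep(LIMBS, each = n),
    phase = fidx / frames_per_cycle,
    freq_hz = frame_rate / frames_per_cycle
  )
  phase$swing <- as.integer(fidx < k_swing)
  if (jitter_frames > 0) {
    phase$swing <- withr::with_seed(seed, {
      unlist(lapply(seq_along(LIMBS), function(i) {
        onsets <- (seq_len(n_cycles + 1) - 1 - 1) * frames_per_cycle - k_off[i]
        onsets <- onsets + sample(-jitter_frames:jitter_frames,
                                  length(onsets), replace = TRUE)
        sw <- integer(n)
        for (o in onsets) {
          idx <- (o + 1):(o + k_swing)
          idx <- idx[idx >= 1 & idx <= n]
          sw[idx] <- 1L
        }
        sw
      }))
    })
  }
  list(raster = dplyr::select(phase, "frame", "limb", "swing"),
       phase = dplyr::arrange(phase, .data$frame, .data$limb))
}
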