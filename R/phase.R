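#' Estimate instantaneous limb phase by the analytic-signal method
#'
#' For each limb, the position parallel to the body axis is
#' mean-subtracted per bout, its discrete-time analytic signal is formed
#' via the FFT (optionally after a 10% cosine taper at bout edges), and
#' the instantaneous phase is the argument of that complex signal,
#' unwrapped, smoothed with a third-order Savitzky-Golay filter (window
#' 15 frames), and rewrapped to cycles on `[0, 1)`. Instantaneous
#' frequency (Hz) comes from the corresponding Savitzky-Golay
#' differentiating filter applied to the unwrapped phase.
#'
#' Phase zero corresponds to the maximally posterior point of the limb
#' cycle; swing (anterior motion) occupies phases below one half.
#'
#' @param limbs limb table; an optional `bout` column splits the record
#'   into separately transformed bouts.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length (frames).
#' @param frame_rate frames per second.
#' @param taper_frac cosine-taper fraction applied per bout edge before
#'   the transform (0 disables).
#' @return tibble `frame`, `limb`, `phase` (cycles), `freq_hz`,
#'   `amplitude` (analytic-signal magnitude, mm).
#' @export
estimate_phase <- function(limbs, sg_order = 3, sg_window = 15, frame_rate = 150,
                           taper_frac = 0.1) {
  check_limb_df(limbs)
  limbs <- dplyr::arrange(limbs, .data$limb, .data$frame)
  if (!"bout" %in% names(limbs)) limbs$bout <- 1L
  limbs |>
    dplyr::group_by(.data$limb, .data$bout) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n <= sg_window)
        stop("bout shorter than the Savitzky-Golay window", call. = FALSE)
      s <- d$x_par - mean(d$x_par)
      if (stats::sd(s) < 1e-12)
        stop("constant limb signal: phase undefined", call. = FALSE)
      if (taper_frac > 0) {
        w <- cosine_taper(n, taper_frac)
        sa <- analytic_signal(s * w)
      } else {
        sa <- analytic_signal(s)
      }
      # the raw argument is pi at the maximally posterior point; shift by
      # half a cycle so that phase zero is the posterior extreme
      raw <- signal::unwrap(Arg(sa)) - pi
      sm <- signal::sgolayfilt(raw, p = sg_order, n = sg_window)
      dfilt <- signal::sgolay(p = sg_order, n = sg_window, m = 1)
      dphi <- signal::sgolayfilt(raw, dfilt)
      tibble::tibble(
        frame = d$frame,
        phase = rad_to_cycles(sm),
        freq_hz = dphi * frame_rate / (2 * pi),
        amplitude = Mod(sa)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("frame", "limb", "phase", "freq_hz", "amplitude") |>
    dplyr::arrange(.data$frame, .data$limb)
}

cosine_taper <- function(n, frac) {
  w <- rep(1, n)
  m <- floor(frac * n)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

#' Canonical limb pairs for relative-phase analysis
#'
#' The six pairings: three contralateral (L1-R1, L2-R2, L3-R3) and three
#' ipsilateral groupings (mid-fore, hind-mid, hind-fore; each pooling
#' left and right instances).
#' @return tibble `pair`, `limb_a`, `limb_b` (phase difference is
#'   `limb_a - limb_b`).
#' @export
limb_pairs <- function() {
  tibble::tibble(
    pair = c("L1-R1", "L2-R2", "L3-R3",
             "M-F", "M-F", "H-M", "H-M", "H-F", "H-F"),
    limb_a = c("L1", "L2", "L3", "L2", "R2", "L3", "R3", "L3", "R3"),
    limb_b = c("R1", "R2", "R3", "L1", "R1", "L2", "R2", "L1", "R1")
  )
}

#' Circular statistics of pairwise relative limb phases
#'
#' Relative phase is the frame-wise difference of two limbs'
#' instantaneous phases, expressed in fractions of a cycle. For each
#' pair and forward-velocity bin this returns the circular mean, mean
#' resultant length, and angular deviation `sqrt(2(1-R))` (cycles), plus
#' optionally a von Mises kernel density estimate.
#'
#' @param phase phase table from [estimate_phase()].
#' @param body optional body table supplying `v_par` for binning; when
#'   absent a single unconditioned bin is reported.
#' @param pairs pair definition tibble, see [limb_pairs()].
#' @param speed_bins speed-bin tibble as from [speed_terciles()], or
#'   `NULL` for no conditioning.
#' @param density also return circular KDEs per pair and bin?
#' @param walking_threshold minimum forward speed (mm/s) when `body` is
#'   supplied.
#' @return tibble `pair`, `speed_bin`, `mean`, `R`, `ang_dev`, `n` (and
#'   a `density` list-column when requested). Empty bins are reported
#'   with `n = 0` and missing moments.
#' @export
relative_phase_stats <- function(phase, body = NULL, pairs = limb_pairs(),
                                 speed_bins = speed_terciles(), density = FALSE,
                                 walking_threshold = 0.5) {
  wide <- phase |>
    dplyr::select("frame", "limb", "phase") |>
    tidyr::pivot_wider(names_from = "limb", values_from = "phase")
  if (!is.null(body)) {
    v <- body$v_par[match(wide$frame, body$frame)]
    wide <- wide[!is.na(v) & v >= walking_threshold, ]
    v <- v[!is.na(v) & v >= walking_threshold]
    wide$speed_bin <- if (is.null(speed_bins)) factor("all") else bin_speed(v, speed_bins)
  } else {
    wide$speed_bin <- factor("all")
  }
  levels_used <- levels(wide$speed_bin)
  # pool all instances of a pair label (ipsilateral groupings have a
  # left and a right instance) before taking circular moments
  purrr::map_dfr(unique(pairs$pair), function(pl) {
    inst <- pairs[pairs$pair == pl, ]
    dphi <- unlist(purrr::map2(inst$limb_a, inst$limb_b,
                               function(a, b) (wide[[a]] - wide[[b]]) %% 1))
    bins <- rep(as.character(wide$speed_bin), nrow(inst))
    purrr::map_dfr(levels_used, function(bn) {
      x <- dphi[bins == bn]
      m <- circ_moments(x)
      row <- dplyr::bind_cols(tibble::tibble(pair = pl, speed_bin = bn), m)
      if (density) row$density <- if (m$n > 0) list(circ_kde(x)) else list(NULL)
      row
    })
  })
}

#' Feet-down count as a function of limb phase
#'
#' Conditional distribution of the number of feet in stance versus the
#' phase of a reference limb (midlimb by default), normalized so that
#' the integral over phase of the sum of the per-count distributions is
#' one. The dominant harmonic is the `k` in 1..6 maximizing the Fourier
#' magnitude of the phase-binned mean feet-down modulation; canonical
#' tripod timing yields 2, a pure wave gait 6.
#'
#' @param raster swing/stance table.
#' @param phase phase table.
#' @param ref_limb reference limb label.
#' @param body optional body table for speed binning.
#' @param speed_bins speed bins (or `NULL` for one bin).
#' @param n_bins number of phase bins.
#' @param walking_threshold minimum forward speed when `body` given.
#' @return list of class `feet_down_phase`: `distribution` (speed_bin,
#'   phase_bin, feet_down, rel_prob), `harmonic` (speed_bin,
#'   dominant_harmonic, modulation amplitude), `n_frames`.
#' @export
feet_down_vs_phase <- function(raster, phase, ref_limb = "L2", body = NULL,
                               speed_bins = NULL, n_bins = 48,
                               walking_threshold = 0.5) {
  fd <- raster |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(feet_down = sum(1 - .data$swing), .groups = "drop")
  ref <- phase[phase$limb == ref_limb, c("frame", "phase")]
  d <- dplyr::inner_join(fd, ref, by = "frame")
  if (!is.null(body)) {
    v <- body$v_par[match(d$frame, body$frame)]
    keep <- !is.na(v) & v >= walking_threshold
    d <- d[keep, ]
    d$speed_bin <- if (is.null(speed_bins)) factor("all") else bin_speed(v[keep], speed_bins)
  } else {
    d$speed_bin <- factor("all")
  }
  if (nrow(d) == 0) stop("no frames with both raster and phase", call. = FALSE)
  d$phase_bin <- floor(d$phase * n_bins) / n_bins + 0.5 / n_bins

  distribution <- d |>
    dplyr::count(.data$speed_bin, .data$phase_bin, .data$feet_down) |>
    dplyr::group_by(.data$speed_bin) |>
    # sum over feet-down counts of the integral over phase equals one
    dplyr::mutate(rel_prob = .data$n / sum(.data$n) * n_bins) |>
    dplyr::ungroup()

  # Dominant periodicity of the per-count conditional distributions,
  # computed per frame (binning the discretely-sampled phase aliases
  # badly when the per-frame phase step approaches the bin width). For
  # each feet-down count c the indicator I(fd = c) is Fourier-analysed
  # in the reference phase; magnitudes are pooled over counts weighted
  # by the count probabilities, so sign-symmetric deviations (a count
  # going both up and down at transitions) register at the transition
  # periodicity.
  harmonic <- d |>
    dplyr::group_by(.data$speed_bin) |>
    dplyr::group_modify(function(g, key) {
      counts <- sort(unique(g$feet_down))
      mag_tbl <- function(mags) {
        names(mags) <- paste0("mag", 1:6)
        tibble::as_tibble(as.list(mags))
      }
      if (length(counts) < 2) {
        return(dplyr::bind_cols(
          tibble::tibble(dominant_harmonic = NA_integer_, amplitude = 0,
                         degenerate = TRUE), mag_tbl(rep(0, 6))))
      }
      ph <- g$phase
      mags <- rep(0, 6)
      for (cc in counts) {
        ind <- as.numeric(g$feet_down == cc)
        p_c <- mean(ind)
        mk <- vapply(1:6, function(k) {
          2 * Mod(mean((ind - p_c) * exp(-2i * pi * k * ph)))
        }, numeric(1))
        mags <- mags + p_c * mk
      }
      dplyr::bind_cols(
        tibble::tibble(dominant_harmonic = which.max(mags),
                       amplitude = max(mags), degenerate = FALSE),
        mag_tbl(mags))
    }) |>
    dplyr::ungroup()

  structure(list(distribution = distribution, harmonic = harmonic,
                 n_frames = nrow(d), ref_limb = ref_limb),
            class = "feet_down_phase")
}

#' @method print feet_down_phase
#' @export
print.feet_down_phase <- function(x, ...) {
  cat("Feet-down vs", x$ref_limb, "phase:", x$n_frames, "frames\n")
  print(x$harmonic)
  invisible(x)
}
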