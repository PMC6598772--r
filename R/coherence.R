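#' Canonical gait phase templates
#'
#' Template phases (cycles) of the four canonical hexapod gaits in limb
#' order L1, L2, L3, R1, R2, R3:
#' tripod `[0, 1/2, 0, 1/2, 0, 1/2]`,
#' left tetrapod `[1/3, 2/3, 0, 0, 1/3, 2/3]`,
#' right tetrapod `[2/3, 0, 1/3, 0, 1/3, 2/3]`,
#' wave `[1/6, 1/3, 1/2, 2/3, 5/6, 0]`.
#'
#' @return tibble with `template`, `limb`, `psi` (cycles). `template` is
#'   a factor whose level order (tripod, left tetrapod, right tetrapod,
#'   wave) is also the tie-breaking priority used by
#'   [best_gait_fraction()].
#' @export
gait_templates <- function() {
  nm <- c("tripod", "left_tetrapod", "right_tetrapod", "wave")
  tibble::tibble(
    template = factor(rep(nm, each = 6), levels = nm),
    limb = rep(LIMBS, times = 4),
    psi = c(0, 1/2, 0, 1/2, 0, 1/2,
            1/3, 2/3, 0, 0, 1/3, 2/3,
            2/3, 0, 1/3, 0, 1/3, 2/3,
            1/6, 1/3, 1/2, 2/3, 5/6, 0)
  )
}

#' Kuramoto-style coherence against a gait template
#'
#' For the six instantaneous limb phases `phi_k(t)` and template phases
#' `psi_k`, the coherence `r(t)` and global phase `Phi(t)` are defined
#' by `r exp(i 2 pi Phi) = (1/6) sum_k exp(i 2 pi (phi_k - psi_k))`.
#' `r` ranges from zero (asynchrony) to one (exact match to the
#' template) and is invariant to adding a common constant to all six
#' phases. Frames with any missing limb phase are marked invalid
#' (`r = NA`).
#'
#' @param phase phase table from [estimate_phase()] (or simulator truth).
#' @param template template name (see [gait_templates()]) or a
#'   six-row tibble with `limb` and `psi`.
#' @return tibble `frame`, `template`, `r`, `Phi` (cycles).
#' @export
template_coherence <- function(phase, template = "tripod") {
  if (is.character(template)) {
    tname <- match.arg(template, levels(gait_templates()$template))
    tmpl <- gait_templates() |> dplyr::filter(.data$template == tname)
  } else {
    tmpl <- template
    tname <- if ("template" %in% names(tmpl)) as.character(tmpl$template[1]) else "custom"
  }
  psi <- tmpl$psi[match(LIMBS, tmpl$limb)]
  wide <- phase |>
    dplyr::select("frame", "limb", "phase") |>
    tidyr::pivot_wider(names_from = "limb", values_from = "phase") |>
    dplyr::arrange(.data$frame)
  if (!all(LIMBS %in% names(wide)))
    stop("phase table must contain all six limbs", call. = FALSE)
  phi <- as.matrix(wide[, LIMBS])
  z <- rowMeans(exp(2i * pi * sweep(phi, 2, psi)))
  z[!stats::complete.cases(phi)] <- NA_complex_
  tibble::tibble(
    frame = wide$frame,
    template = tname,
    r = Mod(z),
    Phi = rad_to_cycles(Arg(z))
  )
}

#' Best-matching canonical gait per frame
#'
#' Computes all four template coherences, assigns each frame to the
#' template with the largest coherence (exact ties broken by the fixed
#' priority tripod > left tetrapod > right tetrapod > wave and counted
#' in `n_ties`), and summarises per speed bin the fraction of frames
#' best described by each template and the mean coherence per template.
#'
#' @param phase phase table.
#' @param body optional body table for speed binning.
#' @param speed_bins speed-bin tibble or `NULL`.
#' @param walking_threshold minimum forward speed when `body` given.
#' @return list of class `gait_fraction`: `per_frame` (frame, best
#'   template, r per template wide), `summary` (speed_bin, template,
#'   fraction, mean_r, n), `n_ties`.
#' @export
best_gait_fraction <- function(phase, body = NULL, speed_bins = speed_terciles(),
                               walking_threshold = 0.5) {
  nm <- levels(gait_templates()$template)
  coh <- purrr::map(nm, function(tn) template_coherence(phase, tn))
  rmat <- do.call(cbind, purrr::map(coh, "r"))
  colnames(rmat) <- nm
  frames <- coh[[1]]$frame
  valid <- stats::complete.cases(rmat)
  best <- rep(NA_character_, length(frames))
  n_ties <- 0L
  if (any(valid)) {
    idx <- apply(rmat[valid, , drop = FALSE], 1, which.max) # first max = priority order
    ties <- apply(rmat[valid, , drop = FALSE], 1,
                  function(r) sum(abs(r - max(r)) < 1e-12) > 1)
    n_ties <- sum(ties)
    best[valid] <- nm[idx]
  }
  per_frame <- dplyr::bind_cols(
    tibble::tibble(frame = frames, best = factor(best, levels = nm)),
    tibble::as_tibble(rmat)
  )
  if (!is.null(body)) {
    v <- body$v_par[match(per_frame$frame, body$frame)]
    keep <- !is.na(v) & v >= walking_threshold
    per_frame <- per_frame[keep, ]
    per_frame$speed_bin <- if (is.null(speed_bins)) factor("all")
                           else bin_speed(v[keep], speed_bins)
  } else {
    per_frame$speed_bin <- factor("all")
  }
  summary <- per_frame |>
    tidyr::pivot_longer(dplyr::all_of(nm), names_to = "template", values_to = "r") |>
    dplyr::group_by(.data$speed_bin, .data$template) |>
    dplyr::summarise(
      fraction = mean(.data$best == .data$template[1], na.rm = TRUE),
      mean_r = mean(.data$r, na.rm = TRUE),
      n = sum(!is.na(.data$r)),
      .groups = "drop"
    )
  structure(list(per_frame = per_frame, summary = summary, n_ties = n_ties),
            class = "gait_fraction")
}

#' @method print gait_fraction
#' @export
print.gait_fraction <- function(x, ...) {
  cat("Best-gait assignment over", nrow(x$per_frame), "frames",
      sprintf("(%d exact ties broken by priority)\n", x$n_ties))
  print(x$summary)
  invisible(x)
}
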