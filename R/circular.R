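#' Circular moments of phases measured in cycles
#'
#' First and second circular moments of a sample of phases on `[0, 1)`
#' cycles. The circular mean is the argument of the complex mean of the
#' unit phasors; the mean resultant length `R` is its magnitude; the
#' angular deviation is `sqrt(2 * (1 - R))`, reported in cycles.
#'
#' @param x numeric vector of phases in cycles.
#' @param na.rm drop missing values?
#' @return `circ_mean()` and `circ_sd()` return scalars (cycles);
#'   `circ_moments()` returns a one-row tibble with `mean`, `R`,
#'   `ang_dev` and `n`.
#' @examples
#' circ_mean(c(0.1, 0.9)) # 0, not 0.5
#' @export
circ_mean <- function(x, na.rm = TRUE) {
  circ_moments(x, na.rm = na.rm)$mean
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x, na.rm = TRUE) {
  circ_moments(x, na.rm = na.rm)$ang_dev
}

#' @rdname circ_mean
#' @export
circ_moments <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(mean = NA_real_, R = NA_real_, ang_dev = NA_real_, n = 0L))
  }
  z <- mean(exp(1i * cycles_to_rad(x)))
  R <- min(Mod(z), 1)
  tibble::tibble(
    mean = rad_to_cycles(Arg(z)),
    R = R,
    ang_dev = rad_to_cycles(sqrt(2 * (1 - R)), wrap = FALSE),
    n = n
  )
}

#' Circular distance between phases
#'
#' Signed shortest distance from `a` to `b` on the circle, in cycles,
#' in `(-0.5, 0.5]`.
#' @param a,b phases in cycles.
#' @export
circ_dist <- function(a, b) {
  d <- (a - b) %% 1
  ifelse(d > 0.5, d - 1, d)
}

#' Circular kernel density estimate with a von Mises kernel
#'
#' Density of circular data on `[0, 1)` cycles, estimated with a von
#' Mises kernel. The density integrates to one over a full cycle. The
#' default concentration follows a Taylor-style plug-in rule computed
#' from the mean resultant length of the sample.
#'
#' @param x phases in cycles.
#' @param at evaluation grid in cycles (default 256 equispaced points).
#' @param kappa von Mises kernel concentration; `NULL` for the plug-in
#'   rule.
#' @return tibble with `phase` and `density` (per cycle).
#' @export
circ_kde <- function(x, at = seq(0, 1, length.out = 257)[-257], kappa = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("empty sample", call. = FALSE)
  if (is.null(kappa)) {
    # plug-in rule of Taylor (2008): kappa_hat from R, then smoothing
    # concentration nu = (3 n kappa^2 I0(2k)... ) simplified power rule
    R <- Mod(mean(exp(1i * cycles_to_rad(x))))
    kappa_hat <- a1inv(min(R, 0.999))
    kappa <- max(
      (3 * n * kappa_hat^2 * besselI(2 * kappa_hat, 0, expon.scaled = TRUE) /
        (4 * sqrt(pi) * besselI(kappa_hat, 0, expon.scaled = TRUE)^2))^(2 / 5),
      1
    )
  }
  th <- cycles_to_rad(x)
  grid <- cycles_to_rad(at)
  dens <- vapply(grid, function(g) {
    mean(exp(kappa * cos(g - th)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) *
      exp(kappa)))
  }, numeric(1))
  # report per cycle rather than per radian so it integrates to 1 on [0,1)
  tibble::tibble(phase = at, density = dens * 2 * pi)
}

# Inverse of A(kappa) = I1(kappa)/I0(kappa) (Fisher 1993 approximation).
a1inv <- function(R) {
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Two-sample Kuiper statistic for circular data
#'
#' `V = D+ + D-`, the sum of the maximal positive and negative
#' deviations between the two empirical CDFs. Unlike Kolmogorov-Smirnov
#' `D`, `V` is invariant to a common rotation of both samples, which
#' makes it the appropriate two-sample statistic on the circle.
#'
#' @param a,b numeric vectors of phases in cycles.
#' @return the statistic (scalar).
#' @export
kuiper_statistic <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  a <- a %% 1
  b <- b %% 1
  pooled <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pooled)
  Fb <- stats::ecdf(b)(pooled)
  d <- Fa - Fb
  max(d, 0) + max(-d, 0)
}

#' Circular-linear and circular-circular association
#'
#' `circ_corr()` is the Fisher-Lee circular-circular correlation
#' coefficient between two phase samples (cycles).
#'
#' @param a,b phases in cycles.
#' @export
circ_corr <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  ta <- cycles_to_rad(a[ok])
  tb <- cycles_to_rad(b[ok])
  num <- sum(sin(ta - mean_dir(ta)) * sin(tb - mean_dir(tb)))
  den <- sqrt(sum(sin(ta - mean_dir(ta))^2) * sum(sin(tb - mean_dir(tb))^2))
  num / den
}

mean_dir <- function(theta) Arg(mean(exp(1i * theta)))
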