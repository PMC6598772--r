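#' Convert phases between cycles and radians
#'
#' A single utility owns the factor 2*pi: phases are stored in cycles on
#' `[0, 1)` throughout the analysis code and in radians only inside the
#' oscillator models.
#'
#' @param x numeric vector of phases.
#' @param wrap wrap the result onto the principal domain (`[0, 1)` cycles
#'   or `[0, 2*pi)` radians)?
#' @return numeric vector.
#' @export
cycles_to_rad <- function(x, wrap = FALSE) {
  out <- x * 2 * pi
  if (wrap) out <- out %% (2 * pi)
  out
}

#' @rdname cycles_to_rad
#' @export
rad_to_cycles <- function(x, wrap = TRUE) {
  out <- x / (2 * pi)
  if (wrap) out <- out %% 1
  out
}

# Centered moving average with shrinking windows at the edges.
# window must be odd; at position i the window is the intersection of
# i +/- half with the record.
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  if (n == 0) return(x)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Zero-phase Gaussian smoothing: convolve forward then backward with a
# normalized Gaussian kernel (sd = sigma samples, truncated at 4 sigma),
# reflecting the series at its ends. The two passes give the squared
# magnitude response exp(-(2*pi*f*sigma)^2).
gaussian_zero_phase <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 2) return(x)
  half <- max(1L, ceiling(4 * sigma))
  if (half >= n) stop("Gaussian kernel (4 sigma) exceeds record length", call. = FALSE)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(y) {
    yp <- c(rev(y[seq_len(half) + 1L]), y, rev(y[n - seq_len(half)]))
    stats::convolve(yp, rev(k), type = "filter")
  }
  rev(pad_filter(rev(pad_filter(x))))
}

# Discrete-time analytic signal via the FFT construction: zero the
# negative frequencies, double the positive ones, keep DC (and Nyquist
# for even lengths) unchanged.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop("analytic signal needs at least 2 samples", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Run-length encoding of a logical vector as a tibble of runs.
logical_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  tibble::tibble(
    value = r$values,
    start = ends - r$lengths + 1L,
    end = ends,
    length = r$lengths
  )
}

# Fan a single user seed out to per-stage seeds, deterministically and
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    sixlimb = 101L, canonical = 211L, scenario = 307L, segments = 401L,
    embedding = 503L, bootstrap = 601L, permutation = 701L, pipeline = 811L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 2017L + off
}

check_limb_df <- function(limbs, need_camera = FALSE) {
  cols <- c("frame", "limb", "x_par", "x_perp")
  missing <- setdiff(cols, names(limbs))
  if (length(missing) > 0)
    stop("limb table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (need_camera && !all(c("x_cam", "y_cam") %in% names(limbs)))
    stop("limb table lacks camera-frame columns x_cam, y_cam", call. = FALSE)
  bad <- setdiff(unique(as.character(limbs$limb)), LIMBS)
  if (length(bad) > 0)
    stop("unknown limb labels: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(limbs)
}
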