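#' Build standardized limb-trajectory segments
#'
#' Randomly samples (seeded) fixed-length windows of the 12 limb
#' coordinate series (6 limbs x 2 egocentric coordinates). With a
#' half-window of `half_window_ms` the window spans `2h + 1` frames, so
#' each segment has `(2h + 1) * 12` dimensions - 372 at the default
#' 100 ms half-window and 150 frames/s. Each variable is mean-subtracted
#' per segment, then every column (timepoint of a variable) is
#' standardized across segments to zero mean and unit variance.
#'
#' @param limbs limb table; an optional `source` column (e.g. gait or
#'   run id) is carried into the metadata, and windows never span
#'   different sources.
#' @param half_window_ms window half-length, ms.
#' @param n_samples number of segments to draw (capped at the number of
#'   available center frames).
#' @param seed RNG seed.
#' @param frame_rate frames per second.
#' @param phase optional phase table; adds mean `freq_hz` over the
#'   window and the central-frame reference-limb phase to the metadata.
#' @param raster optional raster; adds the central-frame feet-down
#'   count.
#' @param ref_limb reference limb for the central phase metadata.
#' @return list of class `segment_matrix`: `matrix` (N x D, standardized),
#'   `meta` (segment_id, source, center_frame, freq_hz, phase_center,
#'   feet_down), `half_window_frames`, plus the column scaling
#'   (`center`, `scale`).
#' @export
build_segments <- function(limbs, half_window_ms = 100, n_samples = 1000, seed = 1,
                           frame_rate = 150, phase = NULL, raster = NULL,
                           ref_limb = "L2") {
  check_limb_df(limbs)
  h <- round(half_window_ms / 1000 * frame_rate)
  win <- 2L * h + 1L
  if (!"source" %in% names(limbs)) limbs$source <- "all"

  wide <- limbs |>
    dplyr::select("frame", "limb", "x_par", "x_perp", "source") |>
    tidyr::pivot_wider(names_from = "limb", values_from = c("x_par", "x_perp")) |>
    dplyr::arrange(.data$source, .data$frame)
  var_cols <- c(paste0("x_par_", LIMBS), paste0("x_perp_", LIMBS))
  stopifnot(all(var_cols %in% names(wide)))

  # candidate centers: full window inside one source record
  n_skipped <- 0L
  cands <- wide |>
    dplyr::group_by(.data$source) |>
    dplyr::mutate(row_in_src = dplyr::row_number(), n_src = dplyr::n()) |>
    dplyr::ungroup()
  ok <- cands$row_in_src > h & cands$row_in_src <= cands$n_src - h
  short <- unique(cands$source[cands$n_src < win])
  n_skipped <- length(short)
  centers_all <- which(ok)
  if (length(centers_all) == 0) stop("no record long enough for the window", call. = FALSE)

  centers <- withr::with_seed(derive_seed(seed, "segments"), {
    if (length(centers_all) <= n_samples) centers_all
    else sort(sample(centers_all, n_samples))
  })

  X <- matrix(NA_real_, nrow = length(centers), ncol = win * 12L)
  vm <- as.matrix(cands[, var_cols])
  for (s in seq_along(centers)) {
    rows <- (centers[s] - h):(centers[s] + h)
    seg <- vm[rows, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) # per-segment, per-variable mean removal
    X[s, ] <- as.vector(seg)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  meta <- tibble::tibble(
    segment_id = seq_along(centers),
    source = cands$source[centers],
    center_frame = cands$frame[centers]
  )
  if (!is.null(phase)) {
    ph <- phase |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(freq_hz = mean(.data$freq_hz), .groups = "drop")
    meta$freq_hz <- ph$freq_hz[match(meta$center_frame, ph$frame)]
    ref <- phase[phase$limb == ref_limb, ]
    meta$phase_center <- ref$phase[match(meta$center_frame, ref$frame)]
  }
  if (!is.null(raster)) {
    fd <- raster |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(feet_down = sum(1 - .data$swing), .groups = "drop")
    meta$feet_down <- fd$feet_down[match(meta$center_frame, fd$frame)]
  }

  structure(list(matrix = Xs, meta = meta, half_window_frames = h,
                 center = ctr, scale = scl, n_sources_skipped = n_skipped),
            class = "segment_matrix")
}

#' @method print segment_matrix
#' @export
print.segment_matrix <- function(x, ...) {
  cat(sprintf("Segment matrix: %d segments x %d dimensions (half-window %d frames)\n",
              nrow(x$matrix), ncol(x$matrix), x$half_window_frames))
  invisible(x)
}

#' Embed segments with UMAP
#'
#' Three-dimensional UMAP embedding of a standardized segment matrix,
#' deterministic under a fixed seed (single-threaded SGD). Neighbor
#' graph hyperparameters are recorded on the result.
#'
#' @param segments `segment_matrix` from [build_segments()].
#' @param dims embedding dimensionality.
#' @param n_neighbors,min_dist UMAP neighbor-graph parameters.
#' @param seed RNG seed.
#' @return tibble of class `manifold_embedding`: metadata columns plus
#'   `e1`..`e<dims>`; attribute `umap_params`.
#' @export
embed_manifold <- function(segments, dims = 3, n_neighbors = 20, min_dist = 0.1,
                           seed = 1) {
  X <- segments$matrix
  if (nrow(X) <= n_neighbors)
    stop("too few segments for the neighbor graph", call. = FALSE)
  emb <- withr::with_seed(derive_seed(seed, "embedding"), {
    uwot::umap(X, n_components = dims, n_neighbors = n_neighbors,
               min_dist = min_dist, metric = "euclidean",
               n_threads = 1, n_sgd_threads = 0, batch = FALSE,
               init = "spectral")
  })
  colnames(emb) <- paste0("e", seq_len(dims))
  out <- dplyr::bind_cols(segments$meta, tibble::as_tibble(emb))
  attr(out, "umap_params") <- list(dims = dims, n_neighbors = n_neighbors,
                                   min_dist = min_dist, metric = "euclidean",
                                   seed = seed)
  class(out) <- c("manifold_embedding", class(out))
  out
}

#' Axial and cyclic manifold coordinates
#'
#' Extracts the manifold's axial coordinate, the cyclic coordinate
#' (angle about the axis), and the density along the axial coordinate.
#' The axis is chosen geometrically among the principal directions of
#' the embedding: the manifold is a hollow tube around its axis, so the
#' axial direction is the one whose perpendicular projection is most
#' annular (largest low-quantile radius relative to the median radius).
#' When frequency/phase metadata are present the Spearman correlation of
#' the axial coordinate with stepping frequency and the circular
#' correlation of the angle with the reference-limb phase are reported.
#'
#' @param embedding `manifold_embedding` tibble.
#' @return list of class `manifold_coordinates`: `coords` (embedding
#'   plus `axial`, `angle` in cycles), `axial_density` (tibble),
#'   `cor_axial_freq` (Spearman rho or NA), `cor_angle_phase` (circular
#'   correlation or NA), `collapsed` (logical flag for degenerate
#'   embeddings).
#' @export
manifold_coordinates <- function(embedding) {
  ecols <- grep("^e\\d+$", names(embedding), value = TRUE)
  E <- as.matrix(embedding[, ecols])
  pc <- stats::prcomp(E, center = TRUE, scale. = FALSE)
  collapsed <- pc$sdev[1] < 1e-8 || (length(pc$sdev) > 2 && pc$sdev[3] < 1e-8)
  if (collapsed) {
    warning("degenerate (collapsed) embedding", call. = FALSE)
  }
  hollowness <- vapply(seq_len(ncol(pc$x)), function(j) {
    r <- sqrt(rowSums(pc$x[, -j, drop = FALSE]^2))
    stats::quantile(r, 0.05, names = FALSE) / stats::median(r)
  }, numeric(1))
  j_ax <- which.max(hollowness)
  ax <- pc$x[, j_ax]
  plane <- pc$x[, setdiff(seq_len(ncol(pc$x)), j_ax)[1:2], drop = FALSE]
  ang <- rad_to_cycles(atan2(plane[, 2], plane[, 1]))
  out <- dplyr::mutate(tibble::as_tibble(embedding), axial = ax, angle = ang)
  dens <- stats::density(ax)
  cor_af <- if ("freq_hz" %in% names(out) && !all(is.na(out$freq_hz)) &&
                stats::sd(out$freq_hz, na.rm = TRUE) > 0) {
    stats::cor(out$axial, out$freq_hz, method = "spearman",
               use = "complete.obs")
  } else NA_real_
  cor_ap <- if ("phase_center" %in% names(out) && !all(is.na(out$phase_center))) {
    circ_corr(out$angle, out$phase_center)
  } else NA_real_
  structure(list(
    coords = out,
    axial_density = tibble::tibble(axial = dens$x, density = dens$y),
    cor_axial_freq = cor_af, cor_angle_phase = cor_ap,
    collapsed = collapsed
  ), class = "manifold_coordinates")
}

#' Connected components of an embedding
#'
#' Builds a k-nearest-neighbor graph on the embedded points, keeps edges
#' shorter than a distance threshold (by default the 99th percentile of
#' the kNN edge lengths), and counts connected components. Distinct
#' gaits produce separated manifolds (more than one component); a single
#' continuum yields one.
#'
#' `n_components` counts components holding at least a small fraction
#' of the points (`min_frac`): isolated points beyond the edge-length
#' cutoff are outliers, not manifolds. All component sizes are returned.
#'
#' @param embedding `manifold_embedding` tibble.
#' @param k neighbors per point.
#' @param threshold edge-length cutoff; `NULL` for the percentile rule.
#' @param percentile percentile of kNN distances used when `threshold`
#'   is `NULL`.
#' @param min_frac minimum fraction of points for a component to count.
#' @return list: `n_components`, `sizes`, `threshold`, `membership`.
#' @export
embedding_components <- function(embedding, k = 10, threshold = NULL,
                                 percentile = 0.99, min_frac = 0.002) {
  ecols <- grep("^e\\d+$", names(embedding), value = TRUE)
  E <- as.matrix(embedding[, ecols])
  nn <- RANN::nn2(E, k = min(k + 1, nrow(E)))
  d <- nn$nn.dists[, -1, drop = FALSE]
  id <- nn$nn.idx[, -1, drop = FALSE]
  if (is.null(threshold)) threshold <- stats::quantile(d, percentile, names = FALSE)
  from <- rep(seq_len(nrow(E)), times = ncol(id))
  to <- as.vector(id)
  keep <- as.vector(d) <= threshold
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(E) - igraph::vcount(g)))
  comp <- igraph::components(g)
  min_size <- max(2, ceiling(min_frac * nrow(E)))
  list(n_components = sum(comp$csize >= min_size),
       sizes = sort(comp$csize, decreasing = TRUE),
       threshold = threshold, membership = comp$membership)
}
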