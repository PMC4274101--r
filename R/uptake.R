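#' Flat-field (x-y sensitivity) correction
#'
#' Corrects smooth spatial biases in detector/illumination sensitivity
#' using an image of a uniformly fluorescing slide: each x-y column is
#' scaled by `mean(calibration) / calibration`, at every z, so the mean
#' intensity of a spatially uniform specimen is preserved.
#'
#' @param channel 3-D array `[x, y, z]` (or x-y matrix).
#' @param calibration Strictly positive x-y matrix matching the channel's
#'   in-plane shape.
#' @return Corrected array of the same shape.
#' @export
correct_flat_field <- function(channel, calibration) {
  calibration <- as.matrix(calibration)
  if (any(!is.finite(calibration)) || any(calibration <= 0))
    stop("correct_flat_field: calibration must be strictly positive ",
         "(bad calibration image)")
  d <- dim(channel)
  if (is.null(d)) stop("correct_flat_field: channel must be a matrix or array")
  if (!all(d[1:2] == dim(calibration)))
    stop("correct_flat_field: calibration and channel x-y shapes differ")
  gain <- mean(calibration) / calibration
  if (length(d) == 2) return(channel * gain)
  out <- channel
  for (i in seq_len(d[3])) out[, , i] <- out[, , i] * gain
  out
}

#' Depth (z) attenuation correction
#'
#' Divides each z-plane by the corresponding gain of a previously
#' calibrated intensity-falloff curve.
#'
#' @param channel 3-D array `[x, y, z]`.
#' @param attenuation_curve Strictly positive gain per z-plane; length at
#'   least the number of planes.
#' @return Corrected array.
#' @export
correct_z_attenuation <- function(channel, attenuation_curve) {
  d <- dim(channel)
  if (is.null(d) || length(d) != 3)
    stop("correct_z_attenuation: channel must be a 3-D array")
  if (length(attenuation_curve) < d[3])
    stop("correct_z_attenuation: attenuation curve shorter than the stack")
  if (any(!is.finite(attenuation_curve[seq_len(d[3])])) ||
      any(attenuation_curve[seq_len(d[3])] <= 0))
    stop("correct_z_attenuation: curve must be strictly positive")
  out <- channel
  for (i in seq_len(d[3])) out[, , i] <- out[, , i] / attenuation_curve[i]
  out
}

# Otsu threshold on a non-negative intensity sample: maximizes
# between-class variance over a 256-bin histogram.  Computed on
# log-compressed intensities (log1p) so that rare, very bright glare
# foci cannot dominate the between-class variance and drag the
# threshold above the wall signal; the returned threshold is on the raw
# intensity scale.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- log1p(v[is.finite(v) & v >= 0])
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(
    as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  expm1(mids[which.max(bc)])
}

# 3x3 median filter of an x-y matrix (edge-replicated), computed with a
# median-of-9 sorting network of vectorized pmin/pmax operations
median_filter_3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- m[c(1, seq_len(nx), nx), c(1, seq_len(ny), ny)]
  x <- vector("list", 9)
  for (k in seq_len(9)) {
    di <- (k - 1) %% 3; dj <- (k - 1) %/% 3
    x[[k]] <- pad[di + seq_len(nx), dj + seq_len(ny)]
  }
  sp <- function(i, j) {
    lo <- pmin(x[[i]], x[[j]]); x[[j]] <<- pmax(x[[i]], x[[j]])
    x[[i]] <<- lo
  }
  # classic 19-exchange network; x[[5]] ends up as the median
  sp(2, 3); sp(5, 6); sp(8, 9); sp(1, 2); sp(4, 5); sp(7, 8)
  sp(2, 3); sp(5, 6); sp(8, 9); sp(1, 4); sp(6, 9); sp(5, 8)
  sp(4, 7); sp(2, 5); sp(3, 6); sp(5, 8); sp(5, 3); sp(7, 5)
  sp(5, 3)
  x[[5]]
}

#' Detect the luminal surface by thresholding the autofluorescence channel
#'
#' For each (x, y) column, the surface is the first z-plane (counting
#' from the luminal face, z index 0) whose intensity reaches the
#' threshold.  The default threshold is Otsu's method computed per stack;
#' a fixed threshold can be supplied instead.  Planes are optionally
#' 3 x 3 median filtered before thresholding to resist glare foci.
#'
#' @param channel Autofluorescence 3-D array `[x, y, z]`.
#' @param threshold `"otsu"` (default) or a fixed non-negative number.
#' @param z_spacing Plane spacing in micron (default 1, i.e. depths in
#'   plane units).
#' @param median_filter Apply a 3 x 3 median filter to each plane before
#'   thresholding (default `TRUE`).
#' @return A `depth_map`: matrix of surface depths in micron
#'   (`index * z_spacing`, 0-based), `NA` where no voxel reaches the
#'   threshold, with attributes `threshold` and `z_spacing`.
#' @export
detect_luminal_surface <- function(channel, threshold = "otsu",
                                   z_spacing = 1, median_filter = TRUE) {
  d <- dim(channel)
  if (is.null(d) || length(d) != 3 || any(d == 0))
    stop("detect_luminal_surface: channel must be a non-empty 3-D array")
  stopifnot(z_spacing > 0)
  work <- channel
  if (median_filter)
    for (i in seq_len(d[3])) work[, , i] <- median_filter_3x3(work[, , i])
  if (identical(threshold, "otsu")) {
    thr <- otsu_threshold(as.numeric(channel))
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
      stop("detect_luminal_surface: invalid threshold")
    thr <- threshold
  }
  # first suprathreshold plane per column, scanning from the luminal face
  idx <- matrix(NA_integer_, d[1], d[2])
  for (i in seq_len(d[3])) {
    hit <- is.na(idx) & (work[, , i] >= thr)
    idx[hit] <- i
  }
  if (all(is.na(idx)))
    warning("detect_luminal_surface: no column reaches the threshold")
  depth <- (idx - 1L) * z_spacing
  structure(depth, threshold = thr, z_spacing = z_spacing,
            class = c("depth_map", class(depth)))
}

#' Depth-windowed maximum intensity projection
#'
#' At each (x, y), takes the maximum intensity over the voxels whose
#' depth from the detected luminal surface lies within the closed window
#' (default 0-25 micron into the wall).  Columns with a missing surface
#' are missing in the output.
#'
#' @param channel 3-D array `[x, y, z]`.
#' @param depth_map Surface depth map in micron from
#'   [detect_luminal_surface()].
#' @param window Closed depth window `[lo, hi]` in micron from the
#'   surface (default `c(0, 25)`).
#' @param z_spacing Plane spacing in micron; defaults to the depth map's
#'   attribute.
#' @return x-y matrix of windowed maxima (`NA` where the surface is
#'   missing).
#' @export
depth_windowed_max <- function(channel, depth_map, window = c(0, 25),
                               z_spacing = attr(depth_map, "z_spacing")) {
  d <- dim(channel)
  if (is.null(d) || length(d) != 3)
    stop("depth_windowed_max: channel must be a 3-D array")
  if (!all(d[1:2] == dim(depth_map)))
    stop("depth_windowed_max: depth map not aligned with channel")
  if (is.null(z_spacing)) z_spacing <- 1
  if (length(window) != 2 || diff(window) < 0)
    stop("depth_windowed_max: empty window")
  if (window[1] < 0 || window[2] > (d[3] - 1) * z_spacing)
    stop("depth_windowed_max: window extends beyond the stack")
  z_depth <- (seq_len(d[3]) - 1) * z_spacing
  out <- matrix(NA_real_, d[1], d[2])
  surf <- as.numeric(depth_map)
  # loop over planes, vectorized over columns: plane i contributes where
  # z_depth[i] - surface depth lies in the window
  for (i in seq_len(d[3])) {
    rel <- z_depth[i] - surf
    use <- !is.na(rel) & rel >= window[1] & rel <= window[2]
    if (!any(use)) next
    plane <- channel[, , i]
    cur <- out[use]
    out[use] <- pmax(cur, plane[use], na.rm = TRUE)
  }
  out
}

#' Circumferential averaging of an intensity map
#'
#' Averages the windowed-projection map across the circumferential (y)
#' direction at each lengthwise (x) station, ignoring missing pixels, and
#' records how many pixels contributed.  Stations with fewer than
#' `min_fraction` of the circumference present are set missing.
#'
#' @param intensity_map x-y matrix (`NA` = missing).
#' @param x Longitudinal coordinates per row, micron (default row index).
#' @param min_fraction Minimum fraction of circumferential pixels that
#'   must be present (default 0.25).
#' @return An `uptake_profile` data.frame with columns `x_um`,
#'   `intensity`, `n_pixels`.
#' @export
circumferential_average <- function(intensity_map, x = NULL,
                                    min_fraction = 0.25) {
  if (is.null(dim(intensity_map)) || length(intensity_map) == 0)
    stop("circumferential_average: empty map")
  if (is.null(x)) x <- seq_len(nrow(intensity_map))
  n_pixels <- rowSums(!is.na(intensity_map))
  intensity <- rowMeans(intensity_map, na.rm = TRUE)
  intensity[n_pixels == 0] <- NA_real_
  low <- n_pixels < min_fraction * ncol(intensity_map)
  intensity[low] <- NA_real_
  structure(data.frame(x_um = x, intensity = intensity,
                       n_pixels = n_pixels),
            class = c("uptake_profile", "data.frame"))
}

# linear interpolation of a profile onto a new grid (NA outside range)
resample_profile <- function(profile, x_new) {
  ok <- !is.na(profile$intensity)
  if (sum(ok) < 2) stop("resample_profile: too few finite stations")
  stats::approx(profile$x_um[ok], profile$intensity[ok], xout = x_new,
                rule = 1)$y
}

#' Average the two segments of one vessel
#'
#' Each carotid is divided lengthwise into two pieces that are imaged
#' separately; their profiles are averaged pointwise (on the overlap of
#' their x ranges, resampling by linear interpolation when the grids are
#' offset) before any group statistics.
#'
#' @param p1,p2 `uptake_profile` data.frames on the cuff-frame x axis.
#' @return An `uptake_profile` on the overlap grid.
#' @export
average_segments <- function(p1, p2) {
  lo <- max(min(p1$x_um), min(p2$x_um))
  hi <- min(max(p1$x_um), max(p2$x_um))
  if (lo >= hi) stop("average_segments: profiles do not overlap in x")
  x <- p1$x_um[p1$x_um >= lo & p1$x_um <= hi]
  v1 <- resample_profile(p1, x)
  v2 <- resample_profile(p2, x)
  structure(data.frame(x_um = x, intensity = (v1 + v2) / 2,
                       n_pixels = NA_integer_),
            class = c("uptake_profile", "data.frame"))
}

#' Group mean and standard error of per-mouse profiles
#'
#' Pointwise mean and SEM (sample SD / sqrt(n)) across mice, on the
#' common grid of the first profile (others resampled linearly).
#'
#' @param profiles List of `uptake_profile` data.frames, one per mouse.
#' @return data.frame with `x_um`, `mean`, `sem` (NA when n < 2), `n`.
#' @export
group_mean_sem <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  x <- profiles[[1]]$x_um
  mat <- vapply(profiles, resample_profile, numeric(length(x)), x_new = x)
  mat <- matrix(mat, nrow = length(x))
  n <- rowSums(!is.na(mat))
  m <- rowMeans(mat, na.rm = TRUE)
  m[n == 0] <- NA_real_
  sem <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  data.frame(x_um = x, mean = m, sem = sem, n = n)
}

#' Full uptake quantification for one stack
#'
#' Chains flat-field correction, z-attenuation correction, luminal
#' surface detection on the autofluorescence channel, depth-windowed
#' maximum projection of the tracer channel, and circumferential
#' averaging.
#'
#' @param stack An `enface_stack`.
#' @param calibration Uniform-slide image (or `NULL` to skip).
#' @param attenuation z gain curve (or `NULL` to skip).
#' @param window Depth window in micron.
#' @param threshold Surface threshold spec (see
#'   [detect_luminal_surface()]).
#' @param median_filter Median-filter planes before surface detection.
#' @return List with `profile` (an `uptake_profile`), `depth_map`, and
#'   the corrected projection `intensity_map`.
#' @export
quantify_uptake <- function(stack, calibration = NULL, attenuation = NULL,
                            window = c(0, 25), threshold = "otsu",
                            median_filter = TRUE) {
  stopifnot(inherits(stack, "enface_stack"))
  tracer <- stack$tracer
  auto <- stack$auto
  if (!is.null(calibration)) {
    tracer <- correct_flat_field(tracer, calibration)
    auto <- correct_flat_field(auto, calibration)
  }
  if (!is.null(attenuation)) {
    tracer <- correct_z_attenuation(tracer, attenuation)
    auto <- correct_z_attenuation(auto, attenuation)
  }
  dm <- detect_luminal_surface(auto, threshold = threshold,
                               z_spacing = stack$z_spacing,
                               median_filter = median_filter)
  proj <- depth_windowed_max(tracer, dm, window = window,
                             z_spacing = stack$z_spacing)
  prof <- circumferential_average(proj, x = stack$x_um)
  list(profile = prof, depth_map = dm, intensity_map = proj)
}
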