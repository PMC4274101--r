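#' True longitudinal uptake profile used by the stack generator
#'
#' Baseline uptake plus (for cuffed vessels) two smoothed top-hat peaks:
#' one centred on the upstream cuff margin and one centred 0.5 mm
#' downstream of the cuff, each about one cuff length wide.  Peaks are
#' Gaussian-convolved rectangles, i.e. built from error functions.
#'
#' @param x Longitudinal positions in micron (cuff frame, narrow end at 0).
#' @param cuff A [cuff_spec()].
#' @param cuffed Logical; `FALSE` gives a flat (uncuffed) profile.
#' @param baseline Baseline wall uptake, arbitrary fluorescence units.
#' @param upstream_amplitude,downstream_amplitude Peak heights above
#'   baseline.
#' @param peak_width_um Full width of the underlying rectangle; defaults
#'   to the cuff length.
#' @param peak_sigma_um Gaussian smoothing scale of the peak edges.
#' @param lname Logical; the nitric-oxide-synthase-inhibition scenario:
#'   both peak amplitudes are set to their mean (upstream/downstream
#'   difference removed) and the baseline is halved.
#' @return List with `intensity` (profile at `x`) and `peak_centers`
#'   (named vector, micron; `NULL` when `cuffed = FALSE`).
#' @export
true_uptake_profile <- function(x, cuff = cuff_spec(), cuffed = TRUE,
                                baseline = 100,
                                upstream_amplitude = 400,
                                downstream_amplitude = 250,
                                peak_width_um = NULL,
                                peak_sigma_um = 150,
                                lname = FALSE) {
  stopifnot(baseline >= 0, upstream_amplitude >= 0, downstream_amplitude >= 0)
  if (is.null(peak_width_um)) peak_width_um <- cuff$length
  if (lname) {
    m <- mean(c(upstream_amplitude, downstream_amplitude))
    upstream_amplitude <- downstream_amplitude <- m
    baseline <- baseline / 2
  }
  if (!cuffed)
    return(list(intensity = rep(baseline, length(x)), peak_centers = NULL))
  ext <- cuff_extent(cuff)
  centers <- c(upstream = ext[1], downstream = ext[2] + 500)
  smoothed_tophat <- function(x, center, width, sigma) {
    a <- center - width / 2
    b <- center + width / 2
    0.5 * (pracma::erf((x - a) / (sqrt(2) * sigma)) -
           pracma::erf((x - b) / (sqrt(2) * sigma)))
  }
  y <- baseline +
    upstream_amplitude *
      smoothed_tophat(x, centers["upstream"], peak_width_um, peak_sigma_um) +
    downstream_amplitude *
      smoothed_tophat(x, centers["downstream"], peak_width_um, peak_sigma_um)
  list(intensity = y, peak_centers = centers)
}

#' Generate a synthetic en-face two-channel confocal stack
#'
#' Emulates an opened half-vessel mounted luminal side down and imaged
#' en face: a curved luminal surface whose depth varies across the
#' circumferential (y) direction, a tracer channel that follows the true
#' longitudinal uptake profile and decays with depth into the wall, and an
#' autofluorescence channel with a low uniform wall signal plus bright
#' glare foci at the cuff margins.  Both channels are then degraded by a
#' smooth multiplicative x-y sensitivity bias, a depth (z) attenuation
#' curve, and shot-like noise.  All signal is laid down on the voxel grid
#' relative to the surface voxel of each column, so that with degradation
#' disabled the analysis pipeline recovers the ground truth exactly.
#'
#' @param cuff A [cuff_spec()].
#' @param cuffed Logical; generate the two-peak cuffed profile or a flat
#'   uncuffed one.
#' @param lname Logical; see [true_uptake_profile()].
#' @param x_range Longitudinal extent imaged, micron (cuff frame).
#' @param vessel_width_um Circumferential extent of the opened half
#'   vessel, micron.
#' @param pixel_size_xy In-plane pixel size, micron (default 3).
#' @param z_spacing Plane spacing, micron.
#' @param n_z Number of planes.
#' @param surface_depth_um Depth of the luminal surface at the vessel
#'   midline, micron.
#' @param surface_sag_um Additional surface depth at the cut edges,
#'   micron (curved mounted surface).
#' @param surface_tilt_um Total surface depth change across the
#'   longitudinal extent, micron (mounting tilt; default 0).
#' @param baseline,upstream_amplitude,downstream_amplitude,peak_width_um,peak_sigma_um
#'   Passed to [true_uptake_profile()].
#' @param decay_length_um Exponential decay length of tracer signal with
#'   depth below the surface, micron.
#' @param autofluorescence_fraction Wall autofluorescence as a fraction of
#'   the tracer baseline (default 0.2).
#' @param glare_amplitude Peak intensity of glare foci in the
#'   autofluorescence channel, as a multiple of the wall
#'   autofluorescence level (glare is much brighter than the wall
#'   signal, but still well below the tracer peaks); 0 disables glare.
#' @param n_glare_foci Number of glare foci per cuff margin per 500
#'   micron of imaged circumference (foci have a fixed areal density, so
#'   narrower strips carry proportionally fewer).
#' @param bias_amplitude Peak fractional amplitude of the smooth
#'   multiplicative x-y sensitivity bias (default 0.1, i.e. 10 percent).
#' @param z_attenuation_length_um Length scale of exponential intensity
#'   falloff with depth; `Inf` for no attenuation.
#' @param noise Shot-noise scale: each voxel value v is perturbed by
#'   Gaussian noise of standard deviation `noise * sqrt(v)` and clamped at
#'   zero. 0 disables noise.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `stack` (class `enface_stack`: `tracer` and `auto`
#'   arrays indexed `[x, y, z]`, pixel sizes, and `x_um`/`y_um` axes),
#'   `truth` (true profile, peak centers, surface maps, bias field,
#'   attenuation curve, seed), `calibration` (simulated uniform-slide
#'   image for flat-field correction) and `attenuation` (the z gain
#'   curve, known exactly).
#' @export
gen_enface_stack <- function(cuff = cuff_spec(), cuffed = TRUE, lname = FALSE,
                             x_range = c(-3100, 3100),
                             vessel_width_um = 500,
                             pixel_size_xy = 3, z_spacing = 5, n_z = 16,
                             surface_depth_um = 10, surface_sag_um = 15,
                             surface_tilt_um = 0,
                             baseline = 100,
                             upstream_amplitude = 400,
                             downstream_amplitude = 250,
                             peak_width_um = NULL, peak_sigma_um = 150,
                             decay_length_um = 40,
                             autofluorescence_fraction = 0.2,
                             glare_amplitude = 8, n_glare_foci = 4,
                             bias_amplitude = 0.1,
                             z_attenuation_length_um = 80,
                             noise = 1,
                             seed) {
  if (missing(seed)) stop("gen_enface_stack: a seed is required")
  stopifnot(pixel_size_xy > 0, z_spacing > 0, n_z >= 2,
            diff(range(x_range)) > 0, vessel_width_um > 0,
            decay_length_um > 0, noise >= 0, bias_amplitude >= 0,
            autofluorescence_fraction >= 0, glare_amplitude >= 0,
            z_attenuation_length_um > 0)
  max_surface <- surface_depth_um + surface_sag_um + abs(surface_tilt_um)
  if (max_surface >= (n_z - 1) * z_spacing)
    stop("gen_enface_stack: surface deeper than the stack extent")

  nx <- max(2L, floor(diff(range(x_range)) / pixel_size_xy))
  ny <- max(2L, floor(vessel_width_um / pixel_size_xy))
  x_um <- min(x_range) + ((seq_len(nx) - 1) + 0.5) * pixel_size_xy
  y_um <- ((seq_len(ny) - 1) + 0.5) * pixel_size_xy

  prof <- true_uptake_profile(x_um, cuff, cuffed, baseline,
                              upstream_amplitude, downstream_amplitude,
                              peak_width_um, peak_sigma_um, lname)

  # continuous surface depth, then quantized to the voxel grid (0-based
  # plane index k: first plane at or below the continuous surface)
  yc <- mean(y_um)
  sag <- surface_sag_um * ((y_um - yc) / (max(y_um) - yc))^2
  tilt <- surface_tilt_um * (x_um - min(x_um)) / diff(range(x_um))
  depth_cont <- outer(tilt + surface_depth_um, sag, `+`)
  k0 <- ceiling(depth_cont / z_spacing)          # 0-based surface plane index
  k0[k0 < 0] <- 0L
  surface_depth <- k0 * z_spacing

  with_seed(seed, {
    # smooth multiplicative x-y sensitivity bias
    if (bias_amplitude > 0) {
      ph <- stats::runif(4, 0, 2 * pi)
      bx <- cos(2 * pi * (x_um - min(x_um)) / diff(range(x_um)) + ph[1]) +
        0.5 * cos(4 * pi * (x_um - min(x_um)) / diff(range(x_um)) + ph[2])
      by <- cos(2 * pi * (y_um - min(y_um)) / diff(range(y_um)) + ph[3]) +
        0.5 * cos(4 * pi * (y_um - min(y_um)) / diff(range(y_um)) + ph[4])
      raw <- outer(bx, by)
      bias <- 1 + bias_amplitude * raw / max(abs(raw))
    } else {
      bias <- matrix(1, nx, ny)
    }

    z_depth <- ((seq_len(n_z) - 1)) * z_spacing
    attenuation <- exp(-z_depth / z_attenuation_length_um)

    # glare foci: 2-D Gaussian blobs in the autofluorescence channel at
    # the cuff margins, extending one plane above the surface
    glare2d <- matrix(0, nx, ny)
    auto_level <- autofluorescence_fraction * baseline
    if (cuffed && glare_amplitude > 0 && n_glare_foci > 0) {
      margins <- cuff_extent(cuff)
      n_foci <- max(1L, round(n_glare_foci * vessel_width_um / 500))
      for (m in margins) {
        for (i in seq_len(n_foci)) {
          cx <- m + stats::runif(1, -100, 100)
          cy <- stats::runif(1, min(y_um), max(y_um))
          s <- stats::runif(1, 15, 30)
          g <- outer(exp(-(x_um - cx)^2 / (2 * s^2)),
                     exp(-(y_um - cy)^2 / (2 * s^2)))
          glare2d <- glare2d + glare_amplitude * auto_level * g
        }
      }
    }

    tracer <- array(0, c(nx, ny, n_z))
    auto <- array(0, c(nx, ny, n_z))
    profile_xy <- matrix(prof$intensity, nx, ny)
    for (i in seq_len(n_z)) {
      rel <- (i - 1L) - k0                       # planes below surface voxel
      inwall <- rel >= 0
      dec <- exp(-pmax(rel, 0) * z_spacing / decay_length_um)
      tr <- profile_xy * dec * inwall
      au <- auto_level * inwall + glare2d * ((i - 1L) >= (k0 - 1L))
      tracer[, , i] <- tr * bias * attenuation[i]
      auto[, , i] <- au * bias * attenuation[i]
    }

    calibration <- 10000 * bias
    if (noise > 0) {
      shot <- function(v) {
        v <- v + noise * sqrt(pmax(v, 0)) * stats::rnorm(length(v))
        v[v < 0] <- 0
        v
      }
      tracer <- array(shot(tracer), dim(tracer))
      auto <- array(shot(auto), dim(auto))
      calibration <- matrix(shot(calibration), nx, ny)
    }

    stack <- structure(
      list(tracer = tracer, auto = auto,
           pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
           x_um = x_um, y_um = y_um),
      class = "enface_stack")
    truth <- list(x = x_um, uptake = prof$intensity,
                  peak_centers = prof$peak_centers,
                  surface_index = k0, surface_depth_um = surface_depth,
                  bias_field = bias, attenuation = attenuation,
                  auto_level = auto_level, seed = seed)
    list(stack = stack, truth = truth,
         calibration = calibration, attenuation = attenuation)
  })
}

#' @export
print.enface_stack <- function(x, ...) {
  d <- dim(x$tracer)
  cat(sprintf(
    "En-face stack: %d x %d x %d voxels (%.0f x %.0f x %.0f um), 2 channels\n",
    d[1], d[2], d[3], d[1] * x$pixel_size_xy, d[2] * x$pixel_size_xy,
    d[3] * x$z_spacing))
  cat(sprintf("  x (cuff frame): %.0f .. %.0f um\n",
              min(x$x_um), max(x$x_um)))
  invisible(x)
}
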