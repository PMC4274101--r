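#' Generate a synthetic carotid lumen geometry around a tapered cuff
#'
#' Builds a centerline plus closed cross-section contours for a vessel
#' carrying a tapered perivascular cuff.  Inside the cuff the lumen is
#' bounded by the cuff's linearly tapering bore minus the wall: with the
#' wall taken as 10 percent of luminal diameter, outer diameter equals
#' 1.2 x luminal diameter, so the maximal lumen inside the cuff is
#' bore / 1.2.  Optional entrance narrowing emulates wall remodelling at
#' the wide end of the cuff, and the throat cross-section can be made
#' elliptical (non-circular stenosis) at constant area.
#'
#' @param cuff A [cuff_spec()].
#' @param vessel_diameter Luminal diameter of the unperturbed vessel,
#'   micron (default 450).  Must be at least 0.8 x the cuff's wide bore.
#' @param entrance_narrowing Fractional reduction in lumen *diameter* at
#'   the cuff's wide end (smooth bump; 0 disables).
#' @param throat_ellipticity Ratio of major to minor axis of the throat
#'   contour (>= 1; 1 gives circles everywhere).  Applied at constant
#'   area, decaying smoothly away from the throat.
#' @param x_range Longitudinal extent, micron (cuff frame).
#' @param n_stations Number of stations along the centerline.
#' @param n_contour_points Vertices per cross-section contour.
#' @param wall_fraction Wall thickness as a fraction of luminal diameter
#'   (default 0.1).
#' @param roughness Fractional random station-to-station diameter
#'   perturbation (smooth, small; 0 disables).
#' @param seed Integer seed.
#' @return List with `geometry` (class `lumen_geometry`: `centerline`
#'   n x 3 matrix, `s` arc-length positions = x, `contours` list of
#'   closed m x 2 polygons in the local cross-section plane) and `truth`
#'   (bore and lumen diameter profiles, throat position, ellipticity
#'   profile, seed).
#' @export
gen_lumen_geometry <- function(cuff = cuff_spec(), vessel_diameter = 450,
                               entrance_narrowing = 0.1,
                               throat_ellipticity = 2,
                               x_range = c(-3500, 1500),
                               n_stations = 201, n_contour_points = 128,
                               wall_fraction = 0.1,
                               roughness = 0, seed = 1) {
  if (n_stations < 2) stop("gen_lumen_geometry: n_stations must be >= 2")
  if (vessel_diameter < cuff$wide_diameter * 0.8)
    stop("gen_lumen_geometry: vessel_diameter must be >= 0.8 x wide bore")
  if (throat_ellipticity < 1)
    stop("gen_lumen_geometry: throat_ellipticity must be >= 1")
  stopifnot(entrance_narrowing >= 0, entrance_narrowing < 1,
            wall_fraction >= 0, wall_fraction < 0.5, roughness >= 0)

  x <- seq(min(x_range), max(x_range), length.out = n_stations)
  bore <- cuff_bore_diameter(cuff, x)
  # maximal lumen inside the cuff: outer = (1 + 2*wall_fraction) * lumen
  lumen_cap <- bore / (1 + 2 * wall_fraction)
  lumen <- pmin(vessel_diameter, lumen_cap, na.rm = TRUE)

  ext <- cuff_extent(cuff)
  wide_end <- if (cuff$orientation == "forward") ext[1] else ext[2]
  if (entrance_narrowing > 0) {
    bump <- exp(-(x - wide_end)^2 / (2 * 300^2))
    lumen <- lumen * (1 - entrance_narrowing * bump)
  }

  withr_state <- with_seed(seed, {
    if (roughness > 0) {
      r <- stats::rnorm(n_stations, 0, roughness)
      r <- stats::filter(r, rep(1 / 5, 5), sides = 2)
      r[is.na(r)] <- 0
      lumen <- lumen * (1 + as.numeric(r))
    }
    lumen
  })
  lumen <- withr_state

  # ellipticity peaks at the throat (x = 0), decaying over ~the taper
  ell <- 1 + (throat_ellipticity - 1) * exp(-x^2 / (2 * 250^2))

  theta <- seq(0, 2 * pi, length.out = n_contour_points + 1)[-1]
  contours <- vector("list", n_stations)
  for (i in seq_len(n_stations)) {
    r_eq <- lumen[i] / 2
    # ellipse of same area as the circle of radius r_eq, aspect ell[i]
    a <- r_eq * sqrt(ell[i])
    b <- r_eq / sqrt(ell[i])
    contours[[i]] <- cbind(a * cos(theta), b * sin(theta))
  }

  geometry <- structure(
    list(centerline = cbind(x, 0, 0), s = x, contours = contours,
         station_spacing = diff(x)[1]),
    class = "lumen_geometry")
  truth <- list(x = x, bore_diameter = bore, lumen_diameter = lumen,
                ellipticity = ell, throat_x = 0,
                wall_fraction = wall_fraction, seed = seed)
  list(geometry = geometry, truth = truth)
}

#' @export
print.lumen_geometry <- function(x, ...) {
  cat(sprintf("Lumen geometry: %d stations over %.0f um (spacing %.1f um)\n",
              length(x$contours), diff(range(x$s)), x$station_spacing))
  invisible(x)
}
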