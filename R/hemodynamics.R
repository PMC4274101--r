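#' Band statistics of a scalar surface field
#'
#' Partitions surface nodes into contiguous half-open longitudinal bands
#' (default 40 micron, anchored at the upstream end of the mapped
#' domain) and reports, per band, the node mean and the "band minimum":
#' the mean of the lower 5th percentile of nodal values (nearest-rank
#' convention, values less than or equal to the 5 percent quantile; for
#' bands with fewer than 20 nodes the set is the single minimum).
#'
#' @param field data.frame with columns `s_um` (longitudinal position)
#'   and `value` (e.g. wall shear stress or pressure, Pa); a `theta_rad`
#'   column may be present but is not used by the banding.
#' @param band_length Band length in micron (default 40).
#' @return data.frame with `band_center`, `mean_value`, `low5_mean`,
#'   `n_nodes` per non-empty band.
#' @export
band_statistics <- function(field, band_length = 40) {
  if (band_length <= 0) stop("band_statistics: band_length must be > 0")
  if (!all(c("s_um", "value") %in% names(field)) || nrow(field) == 0)
    stop("band_statistics: field must have s_um and value columns")
  s0 <- min(field$s_um)
  k <- floor((field$s_um - s0) / band_length)
  idx <- split(seq_len(nrow(field)), k)
  rows <- lapply(names(idx), function(key) {
    v <- field$value[idx[[key]]]
    n <- length(v)
    if (n < 20) {
      low5 <- min(v)
    } else {
      thr <- sort(v)[max(1L, ceiling(0.05 * n))]
      low5 <- mean(v[v <= thr])
    }
    data.frame(band_center = s0 + (as.numeric(key) + 0.5) * band_length,
               mean_value = mean(v), low5_mean = low5, n_nodes = n)
  })
  out <- do.call(rbind, rows)
  out[order(out$band_center), , drop = FALSE]
}

#' Subtract a reference pressure from band means
#'
#' Shifts all band mean pressures so that the band at the reference
#' location reads zero.  The reference is placed a fixed distance
#' downstream of the throat: 2 mm for a forward cuff, 3 mm for a
#' reversed one.
#'
#' @param bands Band summary from [band_statistics()] of a pressure
#'   field.
#' @param throat_s Longitudinal position of the throat, micron.
#' @param orientation `"forward"` or `"reversed"`; sets the default
#'   offset.
#' @param ref_offset Distance of the reference downstream of the throat,
#'   micron; overrides the orientation default.
#' @return Bands with shifted `mean_value` (and `low5_mean` shifted by
#'   the same constant); attribute `reference_s` records the location.
#' @export
subtract_reference_pressure <- function(bands, throat_s = 0,
                                        orientation = c("forward",
                                                        "reversed"),
                                        ref_offset = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(ref_offset))
    ref_offset <- if (orientation == "forward") 2000 else 3000
  ref_s <- throat_s + ref_offset
  if (ref_s < min(bands$band_center) - 20 ||
      ref_s > max(bands$band_center) + 20)
    stop("subtract_reference_pressure: reference outside the banded domain")
  i <- which.min(abs(bands$band_center - ref_s))
  ref <- bands$mean_value[i]
  bands$mean_value <- bands$mean_value - ref
  bands$low5_mean <- bands$low5_mean - ref
  attr(bands, "reference_s") <- bands$band_center[i]
  bands
}

#' Flow split at a bifurcation by Murray's law
#'
#' Flow partitions in proportion to the cubes of the daughter radii.
#'
#' @param radii Non-negative daughter radii (any consistent unit).
#' @return Flow fractions summing to 1.
#' @export
murray_flow_split <- function(radii) {
  if (any(radii < 0)) stop("murray_flow_split: radii must be non-negative")
  cubes <- radii^3
  tot <- sum(cubes)
  if (tot == 0) stop("murray_flow_split: all radii are zero")
  cubes / tot
}

#' Reynolds number
#'
#' `Re = rho * v * D / mu` for mean velocity `v` and diameter `D`.
#'
#' @param v_mean Cross-sectionally averaged velocity, m/s.
#' @param D Diameter, m.
#' @param props A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(v_mean, D, props = fluid_properties()) {
  if (any(D <= 0)) stop("reynolds_number: D must be positive")
  if (any(v_mean < 0)) stop("reynolds_number: v must be non-negative")
  props$rho * v_mean * D / props$mu
}

#' Centreline to cross-sectional mean velocity
#'
#' For fully developed (parabolic, Poiseuille) flow the cross-sectional
#' average is half the centreline velocity.
#'
#' @param v_centerline Centreline velocity (any unit).
#' @return Mean velocity, same unit.
#' @export
centerline_to_mean_velocity <- function(v_centerline) v_centerline / 2

#' Scale a measured velocity to a physiological condition
#'
#' Ultrasound velocities measured under anaesthesia are scaled by 1.05
#' or 1.72 (minimum and maximum reported effects of anaesthesia) to
#' estimate conscious resting values, and by a further 1.88 for active
#' mice.
#'
#' @param v Velocity (any unit).
#' @param condition One of `"anaesthetised"` (identity),
#'   `"conscious_min"` (x 1.05), `"conscious_max"` (x 1.72), `"active"`
#'   (x 1.72 x 1.88).
#' @return Scaled velocity.
#' @export
scale_velocity <- function(v, condition = c("anaesthetised",
                                            "conscious_min",
                                            "conscious_max", "active")) {
  condition <- match.arg(condition)
  f <- switch(condition,
              anaesthetised = 1,
              conscious_min = 1.05,
              conscious_max = 1.72,
              active = 1.72 * 1.88)
  v * f
}

#' Quasi-1D viscous stenosis surrogate
#'
#' Locally Poiseuille flow through a varying-area tube: with equivalent
#' diameter `D(x) = 2 sqrt(A/pi)`, wall shear stress is
#' `tau = 32 mu Q / (pi D^3)` and pressure falls as
#' `dp/dx = -128 mu Q / (pi D^4)` (trapezoidal integration).  Pressure
#' is strictly decreasing — a purely viscous model with no Bernoulli
#' recovery, appropriate at the low Reynolds numbers of the mouse
#' carotid.
#'
#' @param x Longitudinal positions, micron (strictly increasing).
#' @param area Lumen cross-sectional area at `x`, micron^2 (all > 0).
#' @param Q Volumetric flow, m^3/s (> 0).
#' @param props A [fluid_properties()].
#' @param p_in Inlet pressure, Pa (default 0).
#' @return data.frame with `x_um`, `tau_pa` (wall shear stress) and
#'   `p_pa` (pressure).
#' @export
quasi_1d_stenosis <- function(x, area, Q, props = fluid_properties(),
                              p_in = 0) {
  stopifnot(length(x) == length(area), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("quasi_1d_stenosis: x must be increasing")
  if (any(!is.finite(area)) || any(area <= 0))
    stop("quasi_1d_stenosis: area must be positive everywhere")
  if (Q <= 0) stop("quasi_1d_stenosis: flow must be positive")
  area_m2 <- area * 1e-12
  D <- 2 * sqrt(area_m2 / pi)               # m
  tau <- 32 * props$mu * Q / (pi * D^3)     # Pa
  dpdx <- 128 * props$mu * Q / (pi * D^4)   # Pa/m
  x_m <- x * 1e-6
  drop <- cumsum(c(0, diff(x_m) * (dpdx[-1] + dpdx[-length(dpdx)]) / 2))
  data.frame(x_um = x, tau_pa = tau, p_pa = p_in - drop)
}

#' Generate a synthetic scalar field on a tubular lumen surface
#'
#' Evaluates a prescribed longitudinal pattern (optionally modulated
#' circumferentially) at surface nodes of a lumen geometry mapped to
#' rectangular (s, theta) parametric space, plus optional Gaussian
#' noise, and stores per-band ground truth.
#'
#' @param geometry A `lumen_geometry`.
#' @param longitudinal_pattern Function of `s` (micron) returning the
#'   field value (e.g. Pa).
#' @param circumferential_pattern Function of `theta` (radians) returning
#'   a multiplicative modulation (default constant 1).
#' @param noise Gaussian noise standard deviation added per node.
#' @param band_length Band length for the stored truth, micron.
#' @param seed Integer seed.
#' @return List with `field` (data.frame `s_um`, `theta_rad`, `value`)
#'   and `truth` (noise-free band means and low-5th-percentile means).
#' @export
gen_surface_field <- function(geometry, longitudinal_pattern,
                              circumferential_pattern = function(theta)
                                rep(1, length(theta)),
                              noise = 0, band_length = 40, seed = 1) {
  stopifnot(inherits(geometry, "lumen_geometry"))
  npts <- nrow(geometry$contours[[1]])
  theta <- seq(0, 2 * pi, length.out = npts + 1)[-1]
  s <- rep(geometry$s, each = npts)
  th <- rep(theta, times = length(geometry$s))
  base <- longitudinal_pattern(s) * circumferential_pattern(th)
  if (any(!is.finite(base)))
    stop("gen_surface_field: pattern not finite on the domain")
  field <- with_seed(seed, {
    v <- base
    if (noise > 0) v <- v + stats::rnorm(length(v), 0, noise)
    data.frame(s_um = s, theta_rad = th, value = v)
  })
  truth_field <- data.frame(s_um = s, theta_rad = th, value = base)
  truth <- band_statistics(truth_field, band_length)
  list(field = field, truth = truth)
}
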