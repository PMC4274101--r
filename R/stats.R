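#' Subtract a group-mean autofluorescence profile from an uptake profile
#'
#' Pointwise subtraction on the overlap of the two x ranges, resampling
#' the autofluorescence profile by linear interpolation onto the uptake
#' profile's grid.  Negative differences are preserved.
#'
#' @param profile An `uptake_profile` (columns `x_um`, `intensity`).
#' @param auto_profile Autofluorescence profile on the same cuff-frame
#'   axis (columns `x_um` and `intensity` or `mean`).
#' @return An `uptake_profile` restricted to the overlap.
#' @export
subtract_autofluorescence <- function(profile, auto_profile) {
  av <- if ("intensity" %in% names(auto_profile)) auto_profile$intensity
        else auto_profile$mean
  lo <- max(min(profile$x_um), min(auto_profile$x_um))
  hi <- min(max(profile$x_um), max(auto_profile$x_um))
  if (lo >= hi)
    stop("subtract_autofluorescence: x ranges do not overlap")
  keep <- profile$x_um >= lo & profile$x_um <= hi
  x <- profile$x_um[keep]
  a <- stats::approx(auto_profile$x_um, av, xout = x, rule = 1)$y
  structure(data.frame(x_um = x,
                       intensity = profile$intensity[keep] - a,
                       n_pixels = profile$n_pixels[keep]),
            class = c("uptake_profile", "data.frame"))
}

#' Locate the upstream and downstream uptake peaks
#'
#' The upstream peak is sought within `[throat - 2 L, throat - L/2]` and
#' the downstream peak within `[throat, throat + 2 L]`, where `L` is the
#' cuff length and the throat is the cuff's narrow end (x = 0 in the
#' cuff frame).  The maximum locates the peak; because the peaks are
#' broad and flat-topped, the reported centre is the intensity-weighted
#' centroid of the contiguous region around the maximum that stays above
#' 60 percent of the peak's height over the local background, which is
#' far more stable than the raw argmax.  Exact ties are broken toward
#' the cuff and flagged, as are maxima on a region boundary.
#'
#' @param profile An `uptake_profile`.
#' @param cuff A [cuff_spec()].
#' @param throat_x Throat position in the profile's frame (default 0).
#' @param smooth_um Moving-average window applied to the profile before
#'   the argmax (micron; 0 disables).  The peaks are broad and
#'   flat-topped, so without smoothing the argmax of a noisy profile
#'   wanders over the plateau.
#' @return List with `upstream`, `downstream` (each: `center_um`,
#'   `intensity`, `at_boundary`, `tied`).
#' @export
find_uptake_peaks <- function(profile, cuff = cuff_spec(), throat_x = 0,
                              smooth_um = 250) {
  L <- cuff$length
  if (smooth_um > 0 && nrow(profile) > 3) {
    dx <- stats::median(diff(profile$x_um))
    w <- max(1L, round(smooth_um / dx))
    if (w %% 2 == 0) w <- w + 1L
    if (w >= nrow(profile)) w <- 1L
    if (w > 1) {
      sm <- as.numeric(stats::filter(profile$intensity,
                                     rep(1 / w, w), sides = 2))
      keep_na <- is.na(sm)
      sm[keep_na] <- profile$intensity[keep_na]   # edges: unsmoothed
      np <- profile$n_pixels
      if (is.null(np)) np <- NA_integer_
      profile <- structure(
        data.frame(x_um = profile$x_um, intensity = sm, n_pixels = np),
        class = c("uptake_profile", "data.frame"))
    }
  }
  regions <- list(upstream = c(throat_x - 2 * L, throat_x - L / 2),
                  downstream = c(throat_x, throat_x + 2 * L))
  out <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    if (min(profile$x_um) > r[1] || max(profile$x_um) < r[2])
      stop("find_uptake_peaks: profile does not cover the ", nm,
           " search region")
    sel <- which(profile$x_um >= r[1] & profile$x_um <= r[2] &
                   !is.na(profile$intensity))
    if (!length(sel))
      stop("find_uptake_peaks: no finite stations in the ", nm, " region")
    v <- profile$intensity[sel]
    top <- sel[v == max(v)]
    # tie-break toward the cuff: upstream -> largest x, downstream ->
    # smallest x
    i <- if (nm == "upstream") max(top) else min(top)
    tied <- length(top) > 1
    at_boundary <- i == sel[1] || i == sel[length(sel)]
    if (tied || at_boundary) {
      x0 <- profile$x_um[i]
    } else {
      # centroid of the contiguous >= 60%-height region around the max
      bg <- stats::quantile(v, 0.05, names = FALSE)
      thr <- bg + 0.6 * (max(v) - bg)
      high <- v >= thr
      j0 <- which(sel == i)
      lo <- j0; while (lo > 1 && high[lo - 1]) lo <- lo - 1
      hi <- j0; while (hi < length(sel) && high[hi + 1]) hi <- hi + 1
      xs <- profile$x_um[sel[lo:hi]]
      ws <- v[lo:hi] - bg
      x0 <- sum(xs * ws) / sum(ws)
    }
    list(center_um = x0, intensity = profile$intensity[i],
         at_boundary = at_boundary, tied = tied)
  })
  names(out) <- names(regions)
  out
}

#' Mean intensity over a window centred on a peak
#'
#' Mean of the profile over stations with `|x - center| <= width / 2`
#' (default width 700 micron, i.e. the 0.7 mm peak window).
#'
#' @param profile An `uptake_profile`.
#' @param center Window centre, micron.
#' @param width Window width, micron (default 700).
#' @return Mean intensity over the window.
#' @export
window_mean <- function(profile, center, width = 700) {
  stopifnot(width > 0)
  if (center - width / 2 < min(profile$x_um) ||
      center + width / 2 > max(profile$x_um))
    stop("window_mean: window extends beyond the profile")
  sel <- abs(profile$x_um - center) <= width / 2
  mean(profile$intensity[sel], na.rm = TRUE)
}

#' Paired t-test between matched per-mouse values
#'
#' Two-sided Student's paired t-test (e.g. left vs right carotid, or
#' upstream vs downstream peak within mouse).  Zero variance of the
#' differences is flagged rather than producing NaN.
#'
#' @param a,b Equal-length numeric vectors paired by mouse, n >= 2.
#' @return List with `t`, `p`, `df`, `mean_difference`, `n`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired_t_test: unequal lengths")
  n <- length(a)
  if (n < 2) stop("paired_t_test: need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                df = n - 1, mean_difference = mean(d), n = n,
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d), n = n,
       degenerate = FALSE)
}

#' Unpaired (two-sample) t-test
#'
#' Two-sided Student's t-test; pooled variance by default (classical
#' Student), Welch's correction available.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance form (default `FALSE`).
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`, `degenerate`
#'   (TRUE when both groups have zero variance).
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("unpaired_t_test: each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else Inf * sign(d),
                p = if (d == 0) 1 else 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Coefficient of variation of an uptake profile
#'
#' Sample standard deviation divided by the mean of the stationwise
#' intensities along the vessel.
#'
#' @param profile An `uptake_profile`, or a numeric vector of
#'   intensities.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(profile) {
  v <- if (is.data.frame(profile)) profile$intensity else profile
  v <- v[!is.na(v)]
  m <- mean(v)
  if (m <= 0) stop("coefficient_of_variation: mean must be positive")
  stats::sd(v) / m
}
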