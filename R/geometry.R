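#' Resample cross-sections at uniform arc-length stations
#'
#' Re-stations a lumen geometry at a fixed spacing (default 5 micron)
#' along the centerline arc length.  Contours at intermediate positions
#' are obtained by vertex-wise linear interpolation between the two
#' bracketing stored contours; each contour lies in the plane orthogonal
#' to the local (lightly smoothed) centerline tangent.
#'
#' @param geometry A `lumen_geometry`.
#' @param spacing Station spacing in micron (default 5).
#' @return A `lumen_geometry` with stations at uniform spacing.
#' @export
sample_cross_sections <- function(geometry, spacing = 5) {
  stopifnot(inherits(geometry, "lumen_geometry"), spacing > 0)
  cl <- geometry$centerline
  seg <- sqrt(rowSums(diff(cl)^2))
  if (any(seg == 0)) stop("sample_cross_sections: degenerate centerline")
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < spacing)
    stop("sample_cross_sections: centerline shorter than spacing")
  targets <- seq(0, total, by = spacing)

  npts <- nrow(geometry$contours[[1]])
  contours <- vector("list", length(targets))
  centerline <- matrix(0, length(targets), 3)
  for (j in seq_along(targets)) {
    t <- targets[j]
    i <- findInterval(t, s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(s) - 1L)
    w <- (t - s[i]) / (s[i + 1] - s[i])
    centerline[j, ] <- (1 - w) * cl[i, ] + w * cl[i + 1, ]
    contours[[j]] <- (1 - w) * geometry$contours[[i]] +
      w * geometry$contours[[i + 1]]
  }
  structure(
    list(centerline = centerline,
         s = min(geometry$s) + targets,
         contours = contours, station_spacing = spacing),
    class = "lumen_geometry")
}

# TRUE if any two non-adjacent edges of the closed polygon intersect
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  q <- rbind(p, p[1, ])
  ccw <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- q[i, ]; b <- q[i + 1, ]; c <- q[j, ]; d <- q[j + 1, ]
      if (max(a[1], b[1]) < min(c[1], d[1]) ||
          max(c[1], d[1]) < min(a[1], b[1]) ||
          max(a[2], b[2]) < min(c[2], d[2]) ||
          max(c[2], d[2]) < min(a[2], b[2])) next
      if (ccw(a, b, c) * ccw(a, b, d) < 0 &&
          ccw(c, d, a) * ccw(c, d, b) < 0) return(TRUE)
    }
  }
  FALSE
}

#' Area and perimeter of a closed planar contour
#'
#' Area by the shoelace (planar polygon) formula, orientation
#' independent; perimeter as the sum of edge lengths including the
#' closing edge.
#'
#' @param contour m x 2 matrix of vertices (micron), not repeated at the
#'   end.
#' @param check_simple Verify the polygon is simple (non
#'   self-intersecting); on by default.
#' @return List with `area` (micron^2), `perimeter` (micron),
#'   `shape_index` and `centroid`.
#' @export
contour_metrics <- function(contour, check_simple = TRUE) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3)
    stop("contour_metrics: need at least 3 vertices")
  if (check_simple && polygon_self_intersects(contour))
    stop("contour_metrics: polygon is self-intersecting")
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area, perimeter = per,
       shape_index = shape_index(area, per),
       centroid = c(mean(x), mean(y)))
}

#' Shape index of a cross-section
#'
#' `SI = 4 * pi * A / P^2`: 1 for a circle, tending to 0 for a line.
#' Values marginally above 1 from floating-point round-off are clipped to
#' 1; values materially above 1 are an error (they violate the
#' isoperimetric inequality).
#'
#' @param area Cross-sectional area (micron^2), > 0.
#' @param perimeter Contour perimeter (micron), > 0.
#' @return Dimensionless shape index in (0, 1].
#' @export
shape_index <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("shape_index: area and perimeter must be positive")
  si <- 4 * pi * area / perimeter^2
  over <- si > 1
  if (any(si[over] > 1 + 1e-6))
    stop("shape_index: SI > 1; inconsistent area/perimeter")
  si[over] <- 1
  si
}

# minimum distance from each point (n x 2) to the closed polygon boundary
dist_to_polygon_boundary <- function(pts, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  d <- rep(Inf, nrow(pts))
  for (e in seq_len(nrow(a))) {
    ex <- b[e, 1] - a[e, 1]; ey <- b[e, 2] - a[e, 2]
    L2 <- ex^2 + ey^2
    t <- ((pts[, 1] - a[e, 1]) * ex + (pts[, 2] - a[e, 2]) * ey) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[e, 1] + t * ex)
    dy <- pts[, 2] - (a[e, 2] + t * ey)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Maximum inscribed circle of a simple polygon
#'
#' Finds the largest circle fully inside the contour: the interior point
#' maximizing distance to the boundary.  A coarse interior grid seeds a
#' Nelder-Mead refinement of the signed distance; the result is accurate
#' to well within `resolution`.
#'
#' @param contour m x 2 closed simple polygon (micron).
#' @param resolution Target accuracy in micron (default 1).
#' @return List with `center` (x, y) and `radius` (micron).
#' @export
max_inscribed_circle <- function(contour, resolution = 1) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("max_inscribed_circle: degenerate polygon")
  stopifnot(resolution > 0)
  rx <- range(contour[, 1]); ry <- range(contour[, 2])
  n <- 48
  gx <- seq(rx[1], rx[2], length.out = n)
  gy <- seq(ry[1], ry[2], length.out = n)
  pts <- cbind(rep(gx, times = n), rep(gy, each = n))
  inside <- pracma::inpolygon(pts[, 1], pts[, 2],
                              contour[, 1], contour[, 2])
  if (!any(inside)) stop("max_inscribed_circle: no interior points found")
  pin <- pts[inside, , drop = FALSE]
  d <- dist_to_polygon_boundary(pin, contour)
  start <- pin[which.max(d), ]

  signed_neg <- function(p) {
    dd <- dist_to_polygon_boundary(rbind(p), contour)
    s <- if (pracma::inpolygon(p[1], p[2], contour[, 1], contour[, 2]))
      dd else -dd
    -s
  }
  opt <- stats::optim(start, signed_neg, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  list(center = unname(opt$par), radius = unname(-opt$value))
}

#' Wall thickness from paired luminal and adventitial depth maps
#'
#' Thickness is the outer (adventitial) minus inner (luminal) surface
#' depth at each (x, y).  Locations where the surfaces cross (negative
#' thickness) are flagged invalid and returned as `NA`.
#'
#' @param inner,outer Depth maps in micron (matrices of identical shape;
#'   `NA` = missing).
#' @return Matrix of thickness in micron with attribute `n_invalid`
#'   (count of crossing-surface pixels).
#' @export
wall_thickness_map <- function(inner, outer) {
  if (!all(dim(inner) == dim(outer)))
    stop("wall_thickness_map: depth maps have different shapes")
  th <- outer - inner
  invalid <- !is.na(th) & th < 0
  th[invalid] <- NA_real_
  attr(th, "n_invalid") <- sum(invalid)
  th
}

#' Fit the tapered cuff to a lumen geometry
#'
#' Places the cuff's narrow end at the station of minimum equivalent
#' diameter (2 sqrt(A/pi)) and aligns its axis with the line from that
#' point to the centerline point one cuff length upstream (downstream for
#' a reversed cuff).  Also reports the stations where the vessel's outer
#' wall first and last contacts the cuff bore, using the conventions that
#' the wall is 10 percent of luminal diameter and the cast lumen is 10
#' percent smaller than life (resin shrinkage).
#'
#' @param geometry A `lumen_geometry` (resampled internally at
#'   `spacing`).
#' @param cuff A [cuff_spec()].
#' @param spacing Station spacing for the diameter profile, micron.
#' @param wall_fraction Wall thickness as a fraction of luminal diameter.
#' @param shrinkage Cast shrinkage fraction (cast = (1 - shrinkage) x
#'   life).
#' @return List with `throat_s` (arc-length position of the narrow end),
#'   `throat_point`, `axis` (unit vector, upstream to narrow end),
#'   `diameter_profile` (data.frame s, equivalent diameter), and
#'   `contact_s` (range of stations where outer wall >= bore, or `NULL`
#'   if none).
#' @export
fit_cuff <- function(geometry, cuff = cuff_spec(), spacing = 5,
                     wall_fraction = 0.1, shrinkage = 0.1) {
  g <- sample_cross_sections(geometry, spacing)
  if (diff(range(g$s)) <= cuff$length)
    stop("fit_cuff: geometry shorter than the cuff")
  area <- vapply(g$contours, function(cc)
    contour_metrics(cc, check_simple = FALSE)$area, numeric(1))
  deq <- 2 * sqrt(area / pi)
  i_min <- which.min(deq)
  if (i_min == 1L || i_min == length(deq))
    stop("fit_cuff: no interior diameter minimum (no stenosis)")
  throat_s <- g$s[i_min]
  throat_point <- g$centerline[i_min, ]

  dir_sign <- if (cuff$orientation == "forward") -1 else 1
  s_ref <- throat_s + dir_sign * cuff$length
  i_ref <- which.min(abs(g$s - s_ref))
  axis <- throat_point - g$centerline[i_ref, ]
  axis <- axis / sqrt(sum(axis^2))

  # cuff bore along its own axis, narrow end at the throat
  rel <- (g$s - throat_s) * dir_sign        # distance toward the wide end
  bore <- ifelse(rel >= 0 & rel <= cuff$length,
                 cuff$narrow_diameter +
                   (cuff$wide_diameter - cuff$narrow_diameter) *
                   rel / cuff$length,
                 NA_real_)
  lumen_life <- deq / (1 - shrinkage)
  outer_d <- lumen_life * (1 + 2 * wall_fraction)
  contact <- which(!is.na(bore) & outer_d >= bore)
  contact_s <- if (length(contact)) range(g$s[contact]) else NULL

  list(throat_s = throat_s, throat_point = throat_point, axis = axis,
       diameter_profile = data.frame(s = g$s, equivalent_diameter = deq),
       contact_s = contact_s)
}
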