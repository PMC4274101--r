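# Shared fixture builders and brute-force oracles.

# reduced-size stack arguments: full longitudinal coverage for the peak
# search regions, narrow circumferential strip for speed
small_stack_args <- function(...) {
  utils::modifyList(list(x_range = c(-3050, 3050), vessel_width_um = 120),
                    list(...))
}

# degradation fully disabled: pipeline must recover truth exactly
clean_stack_args <- function(...) {
  small_stack_args(noise = 0, bias_amplitude = 0,
                   z_attenuation_length_um = Inf, glare_amplitude = 0,
                   ...)
}

# brute-force per-voxel depth-windowed maximum
oracle_depth_windowed_max <- function(channel, depth_map, window,
                                      z_spacing) {
  d <- dim(channel)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- depth_map[i, j]
    if (is.na(s)) next
    best <- NA_real_
    for (k in seq_len(d[3])) {
      rel <- (k - 1) * z_spacing - s
      if (rel >= window[1] && rel <= window[2]) {
        v <- channel[i, j, k]
        if (is.na(best) || v > best) best <- v
      }
    }
    out[i, j] <- best
  }
  out
}

# brute-force band partition statistics
oracle_band_statistics <- function(field, band_length) {
  s0 <- min(field$s_um)
  k <- floor((field$s_um - s0) / band_length)
  res <- lapply(sort(unique(k)), function(kk) {
    v <- field$value[k == kk]
    low5 <- if (length(v) < 20) min(v) else {
      thr <- sort(v)[ceiling(0.05 * length(v))]
      mean(v[v <= thr])
    }
    data.frame(band_center = s0 + (kk + 0.5) * band_length,
               mean_value = mean(v), low5_mean = low5,
               n_nodes = length(v))
  })
  do.call(rbind, res)
}

# grid distance-transform oracle for the maximum inscribed circle
oracle_inscribed_circle <- function(poly, resolution) {
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  gx <- seq(rx[1], rx[2], by = resolution)
  gy <- seq(ry[1], ry[2], by = resolution)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2])
  pin <- pts[inside, , drop = FALSE]
  d <- cuffmap:::dist_to_polygon_boundary(pin, poly)
  list(center = pin[which.max(d), ], radius = max(d))
}

# random star-shaped polygon around the origin
random_star_polygon <- function(n = 24, r_min = 50, r_max = 250) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}

regular_polygon <- function(n, radius) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(radius * cos(th), radius * sin(th))
}

ellipse_polygon <- function(a, b, n = 2048) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(a * cos(th), b * sin(th))
}
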