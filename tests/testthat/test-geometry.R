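make_cylinder <- function(length_um = 100, radius = 50, n_stations = 11,
                          npts = 64) {
  x <- seq(0, length_um, length.out = n_stations)
  contours <- replicate(n_stations, regular_polygon(npts, radius),
                        simplify = FALSE)
  structure(list(centerline = cbind(x, 0, 0), s = x, contours = contours,
                 station_spacing = diff(x)[1]),
            class = "lumen_geometry")
}

test_that("cross-section resampling yields uniform 5 um stations", {
  cyl <- make_cylinder(100, 50)
  g <- sample_cross_sections(cyl, 5)
  expect_length(g$contours, 21)            # 100/5 + 1
  expect_equal(diff(g$s), rep(5, 20))
  r <- vapply(g$contours, function(cc) mean(sqrt(rowSums(cc^2))),
              numeric(1))
  expect_equal(r, rep(r[1], 21), tolerance = 1e-12)
  bad <- cyl; bad$centerline[3, ] <- bad$centerline[2, ]
  expect_error(sample_cross_sections(bad, 5), "degenerate")
  expect_error(sample_cross_sections(make_cylinder(3, 50), 5), "shorter")
})

test_that("contour metrics match closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- contour_metrics(sq)
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  expect_equal(m$shape_index, pi / 4)
  # orientation independence
  m2 <- contour_metrics(sq[4:1, ])
  expect_equal(m2$area, 1)
  big <- contour_metrics(regular_polygon(4096, 250), check_simple = FALSE)
  expect_lt(abs(big$area - pi * 250^2) / (pi * 250^2), 1e-5)
  expect_error(contour_metrics(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(contour_metrics(bowtie), "self-intersecting")
})

test_that("shape index is 1 for circles and falls toward 0 for lines", {
  big <- contour_metrics(regular_polygon(4096, 250), check_simple = FALSE)
  expect_equal(big$shape_index, 1, tolerance = 1e-4)
  ars <- c(2, 10, 100, 1000)
  si <- vapply(ars, function(ar) {
    e <- ellipse_polygon(sqrt(ar), 1 / sqrt(ar), 4096)
    m <- contour_metrics(e, check_simple = FALSE)
    m$shape_index
  }, numeric(1))
  expect_true(all(diff(si) < 0))
  expect_lt(si[length(si)], 0.01)
  expect_error(shape_index(-1, 4))
  expect_error(shape_index(1, 0))
})

test_that("shape index is scale invariant and bounded by 1", {
  set.seed(3)
  for (k in 1:20) {
    poly <- random_star_polygon()
    m <- contour_metrics(poly, check_simple = FALSE)
    expect_lte(m$shape_index, 1)
    s <- runif(1, 0.1, 10)
    ms <- contour_metrics(poly * s, check_simple = FALSE)
    expect_equal(ms$shape_index, m$shape_index, tolerance = 1e-12)
    expect_equal(ms$area, m$area * s^2, tolerance = 1e-12)
    expect_equal(ms$perimeter, m$perimeter * s, tolerance = 1e-12)
  }
})

test_that("maximum inscribed circle matches known shapes", {
  circ <- regular_polygon(512, 250)
  mic <- max_inscribed_circle(circ, 1)
  expect_equal(mic$radius, 250, tolerance = 1e-2)
  ell <- ellipse_polygon(500, 250, 512)
  expect_equal(max_inscribed_circle(ell, 1)$radius, 250,
               tolerance = 1e-2)
  # r_insc <= equivalent radius, equality only for the circle
  m <- contour_metrics(ell, check_simple = FALSE)
  expect_lt(max_inscribed_circle(ell, 1)$radius, sqrt(m$area / pi))
  expect_error(max_inscribed_circle(rbind(c(0, 0), c(1, 1)), 1))
})

test_that("inscribed circle agrees with the grid distance-transform oracle", {
  set.seed(9)
  for (k in 1:5) {
    poly <- random_star_polygon(18)
    got <- max_inscribed_circle(poly, 1)
    ref <- oracle_inscribed_circle(poly, 2)
    expect_lte(abs(got$radius - ref$radius), 2 * sqrt(2))  # one 2-um cell
    expect_gte(got$radius, ref$radius - 1e-9)  # refinement only improves
  }
})

test_that("wall thickness is outer minus inner depth with crossing flags", {
  inner <- matrix(10, 4, 5)
  outer <- matrix(50, 4, 5)
  th <- wall_thickness_map(inner, outer)
  expect_true(all(th == 40))
  expect_equal(attr(th, "n_invalid"), 0)
  outer2 <- outer; outer2[2, 2] <- 5       # crossing surfaces
  th2 <- wall_thickness_map(inner, outer2)
  expect_true(is.na(th2[2, 2]))
  expect_equal(attr(th2, "n_invalid"), 1)
  expect_error(wall_thickness_map(inner, matrix(1, 3, 5)), "shapes")
})

test_that("wall thinning inside the cuff is recovered from stack truth", {
  # two generated surfaces 40 um apart with a 10 um thinning in the cuff
  g <- gen_enface_stack(cuffed = FALSE, noise = 0, bias_amplitude = 0,
                        z_attenuation_length_um = Inf, glare_amplitude = 0,
                        x_range = c(-500, 500), vessel_width_um = 60,
                        seed = 1)
  inner <- g$truth$surface_depth_um
  thinning <- matrix(0, nrow(inner), ncol(inner))
  thinning[abs(g$truth$x) < 250, ] <- 10
  outer <- inner + 40 - thinning
  th <- wall_thickness_map(inner, outer)
  expect_true(all(th[abs(g$truth$x) < 250, ] == 30))
  expect_true(all(th[abs(g$truth$x) >= 250, ] == 40))
})

test_that("cuff fitting places the throat at the diameter minimum", {
  gl <- gen_lumen_geometry(n_stations = 101, n_contour_points = 48,
                           seed = 4)
  fit <- fit_cuff(gl$geometry, spacing = 25)
  expect_lte(abs(fit$throat_s - 0), 25)    # within one station
  expect_equal(fit$axis, c(1, 0, 0), tolerance = 1e-9)
  # reversed cuff on the mirrored geometry gives the mirrored placement
  rev <- gen_lumen_geometry(cuff = cuff_spec(orientation = "reversed"),
                            x_range = c(-1500, 3500),
                            n_stations = 101, n_contour_points = 48,
                            seed = 4)
  fit_r <- fit_cuff(rev$geometry, cuff_spec(orientation = "reversed"),
                    spacing = 25)
  expect_lte(abs(fit_r$throat_s - 0), 25)
  expect_equal(fit_r$axis, c(-1, 0, 0), tolerance = 1e-9)
  # a straight cylinder has no stenosis to fit
  expect_error(fit_cuff(make_cylinder(2000, 200, 21), spacing = 25),
               "no interior")
})
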