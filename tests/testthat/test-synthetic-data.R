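test_that("cuff spec encodes the linear 500-250 um taper and rejects bad dims", {
  cuff <- cuff_spec()
  expect_equal(cuff_extent(cuff), c(-1500, 0))
  expect_equal(cuff_bore_diameter(cuff, c(-1500, -750, 0)),
               c(500, 375, 250))
  expect_true(is.na(cuff_bore_diameter(cuff, 10)))
  rev <- cuff_spec(orientation = "reversed")
  expect_equal(cuff_extent(rev), c(0, 1500))
  expect_equal(cuff_bore_diameter(rev, c(0, 1500)), c(250, 500))
  expect_error(cuff_spec(wide_diameter = 200, narrow_diameter = 250),
               "wide_diameter")
  expect_error(cuff_spec(length = -1))
})

test_that("stack generator is a pure function of config and seed", {
  a <- gen_enface_stack(x_range = c(-200, 200), vessel_width_um = 60,
                        seed = 42)
  b <- gen_enface_stack(x_range = c(-200, 200), vessel_width_um = 60,
                        seed = 42)
  expect_identical(a$stack$tracer, b$stack$tracer)
  expect_identical(a$stack$auto, b$stack$auto)
  expect_identical(a$calibration, b$calibration)
  c <- gen_enface_stack(x_range = c(-200, 200), vessel_width_um = 60,
                        seed = 43)
  expect_false(identical(a$stack$tracer, c$stack$tracer))
})

test_that("true peaks sit on the upstream margin and 0.5 mm past the cuff", {
  g <- gen_enface_stack(x_range = c(-400, 400), vessel_width_um = 60,
                        seed = 1)
  expect_equal(unname(g$truth$peak_centers),
               c(-1500, 500))
  rev <- gen_enface_stack(cuff = cuff_spec(orientation = "reversed"),
                          x_range = c(-400, 400), vessel_width_um = 60,
                          seed = 1)
  expect_equal(unname(rev$truth$peak_centers), c(0, 2000))
})

test_that("with degradation disabled the recovered profile equals truth", {
  g <- gen_enface_stack(cuffed = FALSE, noise = 0, bias_amplitude = 0,
                        z_attenuation_length_um = Inf, glare_amplitude = 0,
                        x_range = c(-500, 500), vessel_width_um = 90,
                        seed = 5)
  q <- quantify_uptake(g$stack, NULL, NULL, median_filter = FALSE)
  expect_equal(q$profile$intensity, g$truth$uptake, tolerance = 0)
  # two-peak profile too
  g2 <- gen_enface_stack(cuffed = TRUE, noise = 0, bias_amplitude = 0,
                         z_attenuation_length_um = Inf,
                         glare_amplitude = 0,
                         x_range = c(-2000, 1000), vessel_width_um = 90,
                         seed = 5)
  q2 <- quantify_uptake(g2$stack, NULL, NULL, median_filter = FALSE)
  expect_equal(q2$profile$intensity, g2$truth$uptake, tolerance = 0)
})

test_that("non-physical stack parameters are rejected", {
  expect_error(gen_enface_stack(seed = 1, baseline = -5))
  expect_error(gen_enface_stack(seed = 1, n_z = 1))
  expect_error(gen_enface_stack(seed = 1, surface_depth_um = 500),
               "surface deeper")
  expect_error(gen_enface_stack(x_range = c(-100, 100)))  # missing seed
})

test_that("lumen generator bounds the lumen by the tapering cuff bore", {
  gl <- gen_lumen_geometry(seed = 2)
  tr <- gl$truth
  incuff <- tr$x >= -1500 & tr$x <= 0
  # bore reaches 250 um at the narrow end
  expect_equal(min(tr$bore_diameter[incuff]), 250)
  expect_equal(tr$bore_diameter[tr$x == -1500], 500)
  # wall = 10% of luminal diameter: outer = 1.2 x lumen <= bore
  expect_true(all(tr$lumen_diameter[incuff] * 1.2 <=
                    tr$bore_diameter[incuff] + 1e-9))
  # wall thickness 10% of luminal diameter => lumen = bore / 1.2
  throat <- which.min(abs(tr$x))
  expect_equal(tr$lumen_diameter[throat], 250 / 1.2, tolerance = 1e-5)
})

test_that("lumen generator contour shapes honour the ellipticity request", {
  gl <- gen_lumen_geometry(throat_ellipticity = 1, entrance_narrowing = 0,
                           seed = 1)
  si <- vapply(gl$geometry$contours, function(cc)
    contour_metrics(cc, check_simple = FALSE)$shape_index, numeric(1))
  expect_true(all(abs(si - 1) < 1e-3))
  gl2 <- gen_lumen_geometry(throat_ellipticity = 3, seed = 1)
  throat <- which.min(abs(gl2$geometry$s))
  si_throat <- contour_metrics(gl2$geometry$contours[[throat]],
                               check_simple = FALSE)$shape_index
  expect_lt(si_throat, 1)
  expect_error(gen_lumen_geometry(n_stations = 1), "n_stations")
  expect_error(gen_lumen_geometry(throat_ellipticity = 0.5))
  expect_error(gen_lumen_geometry(vessel_diameter = 300), "0.8")
})

test_that("doppler generator stores exact per-beat truth", {
  g <- gen_doppler_trace(noise = 0, breathing_mod = 0, seed = 1)
  b <- segment_beats(g$trace, 7)
  m <- beat_metrics(g$trace, b, 10, denoise = FALSE)
  expect_equal(unname(m$averages["peak_v"]),
               unname(g$truth$mean_metrics["peak_v"]))
  expect_equal(unname(m$averages["edv"]),
               unname(g$truth$mean_metrics["edv"]))
  expect_equal(unname(m$averages["cycle_mean"]),
               unname(g$truth$mean_metrics["cycle_mean"]))
  expect_error(gen_doppler_trace(peak_v = 5, edv_v = 10, seed = 1))
  expect_error(gen_doppler_trace(sample_rate = 100, heart_rate_hz = 7,
                                 seed = 1), "sample rate")
  # determinism
  g2 <- gen_doppler_trace(seed = 4)
  g3 <- gen_doppler_trace(seed = 4)
  expect_identical(g2$trace$v_cm_s, g3$trace$v_cm_s)
})

test_that("10% breathing modulation leaves 10-beat averages within 1%", {
  gm <- gen_doppler_trace(noise = 0, breathing_mod = 0.1, seed = 1)
  g0 <- gen_doppler_trace(noise = 0, breathing_mod = 0, seed = 1)
  mm <- beat_metrics(gm$trace, segment_beats(gm$trace, 7), 10)
  m0 <- beat_metrics(g0$trace, segment_beats(g0$trace, 7), 10)
  expect_true(all(abs(mm$averages - m0$averages) / m0$averages < 0.01))
})

test_that("surface field generator stores band truth and is seeded", {
  gl <- gen_lumen_geometry(n_stations = 51, n_contour_points = 32,
                           seed = 1)
  f <- gen_surface_field(gl$geometry, function(s) rep(7, length(s)),
                         noise = 0, seed = 1)
  b <- band_statistics(f$field, 40)
  expect_true(all(b$mean_value == 7))
  expect_true(all(b$low5_mean == 7))
  # step pattern at the throat lands in the right band
  step <- function(s) ifelse(s < 0, 1, 9)
  fs <- gen_surface_field(gl$geometry, step, noise = 0, seed = 1)
  bs <- band_statistics(fs$field, 40)
  expect_true(all(bs$mean_value[bs$band_center < -40] == 1))
  expect_true(all(bs$mean_value[bs$band_center > 40] == 9))
  # same seed -> identical field
  f2 <- gen_surface_field(gl$geometry, function(s) s, noise = 0.5,
                          seed = 9)
  f3 <- gen_surface_field(gl$geometry, function(s) s, noise = 0.5,
                          seed = 9)
  expect_identical(f2$field$value, f3$field$value)
  expect_error(gen_surface_field(gl$geometry,
                                 function(s) rep(Inf, length(s))),
               "finite")
})
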