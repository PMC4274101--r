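test_that("band statistics implement the nearest-rank lower-5th rule", {
  f <- data.frame(s_um = rep(10, 100), value = 1:100)
  b <- band_statistics(f, 40)
  expect_equal(nrow(b), 1)
  expect_equal(b$mean_value, 50.5)
  expect_equal(b$low5_mean, 3)             # mean of {1..5}
  # uniform field: every band mean and minimum-statistic equal c
  fu <- data.frame(s_um = runif(500, 0, 400), value = 7)
  bu <- band_statistics(fu, 40)
  expect_true(all(bu$mean_value == 7))
  expect_true(all(bu$low5_mean == 7))
  # small bands fall back to the single minimum
  f3 <- data.frame(s_um = c(1, 2, 3), value = c(5, 2, 9))
  expect_equal(band_statistics(f3, 40)$low5_mean, 2)
  expect_error(band_statistics(f, 0), "band_length")
})

test_that("band statistics agree exactly with the brute-force oracle", {
  set.seed(5)
  for (k in 1:4) {
    f <- data.frame(s_um = runif(400, -200, 600),
                    value = rnorm(400))
    got <- band_statistics(f, 40)
    want <- oracle_band_statistics(f, 40)
    expect_equal(got$mean_value, want$mean_value)
    expect_equal(got$low5_mean, want$low5_mean)
    expect_equal(got$n_nodes, want$n_nodes)
    expect_true(all(got$low5_mean <= got$mean_value + 1e-12))
  }
})

test_that("reference pressure subtraction zeroes the reference band", {
  set.seed(6)
  bands <- data.frame(band_center = seq(20, 3980, 40),
                      mean_value = rnorm(100), low5_mean = rnorm(100) - 1,
                      n_nodes = 30)
  out <- subtract_reference_pressure(bands, throat_s = 0, "forward")
  i <- which.min(abs(out$band_center - 2000))
  expect_equal(out$mean_value[i], 0)
  out_r <- subtract_reference_pressure(bands, throat_s = 0, "reversed")
  j <- which.min(abs(out_r$band_center - 3000))
  expect_equal(out_r$mean_value[j], 0)
  # idempotent
  expect_equal(subtract_reference_pressure(out, 0, "forward")$mean_value,
               out$mean_value)
  expect_error(subtract_reference_pressure(bands, throat_s = 3000,
                                           "reversed"),
               "outside")
})

test_that("Murray's law splits flow by cubed radii", {
  expect_equal(murray_flow_split(c(1, 1)), c(0.5, 0.5))
  expect_equal(murray_flow_split(c(1, 2)), c(1 / 9, 8 / 9))
  expect_equal(murray_flow_split(c(0, 2)), c(0, 1))
  expect_error(murray_flow_split(c(0, 0)), "zero")
  # permutation equivariance and unit sum
  set.seed(7)
  r <- runif(4)
  p <- sample(4)
  expect_equal(sum(murray_flow_split(r)), 1)
  expect_equal(murray_flow_split(r)[p], murray_flow_split(r[p]))
})

test_that("Reynolds number and velocity conversions follow the formulas", {
  expect_equal(reynolds_number(0, 1e-3), 0)
  expect_equal(reynolds_number(0.12, 500e-6), 1015 * 0.12 * 500e-6 / 0.004)
  expect_equal(reynolds_number(0.24, 500e-6),
               2 * reynolds_number(0.12, 500e-6))
  expect_error(reynolds_number(0.1, 0))
  expect_equal(centerline_to_mean_velocity(24), 12)
  expect_equal(centerline_to_mean_velocity(0), 0)
  expect_equal(2 * centerline_to_mean_velocity(13), 13)
})

test_that("velocity scalings use the anaesthesia and activity factors", {
  expect_equal(scale_velocity(10, "conscious_min"), 10.5)
  expect_equal(scale_velocity(10, "conscious_max"), 17.2)
  expect_equal(scale_velocity(10, "active"), 10 * 1.72 * 1.88)
  expect_equal(scale_velocity(10, "anaesthetised"), 10)
  expect_error(scale_velocity(10, "sprinting"))
})

test_that("quasi-1D surrogate reproduces Poiseuille on uniform tubes", {
  D <- 500e-6
  A_um2 <- pi * (250)^2
  V <- 0.06
  Q <- V * pi * (D / 2)^2
  x <- seq(0, 5000, 50)
  out <- quasi_1d_stenosis(x, rep(A_um2, length(x)), Q)
  tau_ref <- 8 * 0.004 * V / D
  expect_true(all(abs(out$tau_pa - tau_ref) / tau_ref < 1e-10))
  # pressure linear in x for a uniform tube
  expect_equal(diff(out$p_pa), rep(diff(out$p_pa)[1], length(x) - 1))
  # halving D at fixed Q multiplies tau by 8
  out2 <- quasi_1d_stenosis(x, rep(A_um2 / 4, length(x)), Q)
  expect_equal(out2$tau_pa / out$tau_pa, rep(8, length(x)),
               tolerance = 1e-12)
  expect_error(quasi_1d_stenosis(x, rep(-1, length(x)), Q), "positive")
  expect_error(quasi_1d_stenosis(x, rep(A_um2, length(x)), 0), "flow")
})

test_that("quasi-1D shear peaks at the throat and pressure never recovers", {
  gl <- gen_lumen_geometry(seed = 3)
  tr <- gl$truth
  area <- pi * (tr$lumen_diameter / 2)^2
  out <- quasi_1d_stenosis(tr$x, area, Q = 2e-8)
  expect_equal(out$x_um[which.max(out$tau_pa)],
               tr$x[which.min(tr$lumen_diameter)])
  expect_true(all(diff(out$p_pa) <= 0))
  # property: pressure monotone nonincreasing for random positive areas
  set.seed(11)
  for (k in 1:100) {
    a <- exp(cumsum(rnorm(40, 0, 0.3))) * 1e4
    o <- quasi_1d_stenosis(seq(0, 390, 10), a, Q = 1e-8)
    expect_true(all(diff(o$p_pa) <= 0))
  }
})
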