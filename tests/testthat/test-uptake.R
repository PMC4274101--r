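test_that("flat-field correction divides out the calibration ramp", {
  ch <- array(5, c(4, 3, 2))
  expect_equal(correct_flat_field(ch, matrix(2, 4, 3)), ch)
  # input equal to the ramp itself becomes constant at the ramp mean
  ramp <- matrix(seq(1, 4, length.out = 12), 4, 3)
  ch2 <- array(rep(ramp, 2), c(4, 3, 2))
  out <- correct_flat_field(ch2, ramp)
  expect_equal(as.numeric(out), rep(mean(ramp), 24))
  # elementwise-division oracle on random input
  set.seed(1)
  x <- array(runif(24), c(4, 3, 2))
  out2 <- correct_flat_field(x, ramp)
  for (k in 1:2)
    expect_equal(out2[, , k], x[, , k] * mean(ramp) / ramp)
  bad <- ramp; bad[2, 2] <- 0
  expect_error(correct_flat_field(ch2, bad), "calibration")
  expect_error(correct_flat_field(ch2, matrix(1, 5, 3)), "shape")
})

test_that("flat-field correction is idempotent under constant calibration", {
  set.seed(2)
  x <- array(runif(60), c(5, 4, 3))
  once <- correct_flat_field(x, matrix(3, 5, 4))
  twice <- correct_flat_field(once, matrix(3, 5, 4))
  expect_identical(once, twice)
})

test_that("z-attenuation correction inverts a known decay", {
  x <- array(1, c(3, 3, 5))
  expect_equal(correct_z_attenuation(x, rep(1, 5)), x)
  decay <- exp(-(0:4) / 2)
  degraded <- x
  for (i in 1:5) degraded[, , i] <- degraded[, , i] * decay[i]
  restored <- correct_z_attenuation(degraded, decay)
  expect_lt(max(abs(restored - 1)), 1e-9)
  expect_error(correct_z_attenuation(x, c(1, 1, 0, 1, 1)), "positive")
  expect_error(correct_z_attenuation(x, rep(1, 3)), "shorter")
})

test_that("surface detection reads the first suprathreshold voxel", {
  # step surface at 0-based z-index 5
  ch <- array(0, c(6, 5, 10))
  ch[, , 6:10] <- 100                      # index 6 is 0-based plane 5
  dm <- detect_luminal_surface(ch, z_spacing = 4, median_filter = FALSE)
  expect_true(all(dm == 5 * 4))
  # fixed threshold override
  dm2 <- detect_luminal_surface(ch, threshold = 50, z_spacing = 4,
                                median_filter = FALSE)
  expect_true(all(dm2 == 20))
  expect_error(detect_luminal_surface(ch, threshold = -1), "threshold")
  expect_warning(
    dall <- detect_luminal_surface(array(0, c(3, 3, 4)),
                                   threshold = 10, median_filter = FALSE),
    "no column")
  expect_true(all(is.na(dall)))
})

test_that("the Otsu threshold maximizes between-class variance", {
  set.seed(13)
  v <- c(rnorm(4000, 10, 2), rnorm(2000, 60, 5))
  v <- pmax(v, 0)
  thr <- cuffmap:::otsu_threshold(v)
  # brute-force continuous-sample oracle (in the same log domain)
  lv <- log1p(v)
  grid <- seq(min(lv) + 0.01, max(lv) - 0.01, length.out = 400)
  bc <- vapply(grid, function(t) {
    w0 <- mean(lv < t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(lv[lv < t]) - mean(lv[lv >= t]))^2
  }, numeric(1))
  ref <- expm1(grid[which.max(bc)])
  # same class split as the oracle threshold
  expect_equal(mean(v < thr), mean(v < ref))
  expect_gt(thr, 10)
  expect_lt(thr, 60)
})

test_that("tilted-plane surfaces are recovered within one voxel", {
  g <- gen_enface_stack(cuffed = FALSE, surface_tilt_um = 20,
                        x_range = c(-500, 500), vessel_width_um = 90,
                        seed = 11)
  dm <- detect_luminal_surface(g$stack$auto,
                               z_spacing = g$stack$z_spacing)
  err <- abs(dm - g$truth$surface_depth_um)
  expect_gte(mean(err <= g$stack$z_spacing), 0.99)
})

test_that("depth-windowed max respects the closed 0-25 um window", {
  ch <- array(1, c(4, 4, 12))
  dm <- structure(matrix(0, 4, 4), z_spacing = 5)
  # bright voxel 10 um below the surface is captured at its (x, y)
  ch[2, 3, 3] <- 50                        # 0-based plane 2 = 10 um
  out <- depth_windowed_max(ch, dm, c(0, 25), z_spacing = 5)
  expect_equal(out[2, 3], 50)
  # bright voxel 30 um below the surface is excluded
  ch2 <- array(1, c(4, 4, 12))
  ch2[2, 3, 7] <- 50                       # plane 6 = 30 um
  out2 <- depth_windowed_max(ch2, dm, c(0, 25), z_spacing = 5)
  expect_equal(out2[2, 3], 1)
  expect_error(depth_windowed_max(ch, dm, c(10, 5), z_spacing = 5),
               "window")
})

test_that("depth-windowed max agrees exactly with the brute-force oracle", {
  set.seed(7)
  for (rep in 1:3) {
    ch <- array(runif(6 * 5 * 8), c(6, 5, 8))
    depth <- matrix(sample(c(0, 5, 10, NA), 30, replace = TRUE), 6, 5)
    got <- depth_windowed_max(ch, depth, c(0, 25), z_spacing = 5)
    want <- oracle_depth_windowed_max(ch, depth, c(0, 25), 5)
    expect_identical(got, want)
  }
})

test_that("projection output dominates the in-window median", {
  set.seed(8)
  ch <- array(runif(10 * 6 * 8), c(10, 6, 8))
  depth <- matrix(0, 10, 6)
  out <- depth_windowed_max(ch, depth, c(0, 25), z_spacing = 5)
  med <- apply(ch[, , 1:6], c(1, 2), stats::median)
  expect_true(all(out >= med))
})

test_that("circumferential averaging handles missing pixels and stations", {
  m <- matrix(3, 5, 8)
  p <- circumferential_average(m)
  expect_true(all(p$intensity == 3))
  expect_true(all(p$n_pixels == 8))
  m2 <- matrix(c(1, 2, 3, NA), 1, 4)
  p2 <- circumferential_average(m2, min_fraction = 0.25)
  expect_equal(p2$intensity, 2)
  expect_equal(p2$n_pixels, 3)
  m3 <- matrix(NA_real_, 2, 4)
  p3 <- circumferential_average(m3)
  expect_true(all(is.na(p3$intensity)))
  # stations below the 25% circumference rule are dropped
  m4 <- matrix(NA_real_, 1, 10); m4[1, 1] <- 5
  expect_true(is.na(circumferential_average(m4)$intensity))
})

test_that("segment averaging is a pointwise mean on the overlap", {
  p <- structure(data.frame(x_um = 0:10, intensity = (0:10)^1.5,
                            n_pixels = 5),
                 class = c("uptake_profile", "data.frame"))
  expect_equal(average_segments(p, p)$intensity, p$intensity)
  p3 <- p; p3$intensity <- 3 * p$intensity
  expect_equal(average_segments(p, p3)$intensity, 2 * p$intensity)
  # offset grids: compare against an explicit interpolation oracle
  q <- structure(data.frame(x_um = 0:10 + 0.5,
                            intensity = sin(0:10), n_pixels = 5),
                 class = c("uptake_profile", "data.frame"))
  got <- average_segments(p, q)
  ref <- (p$intensity[p$x_um >= 0.5] +
            approx(q$x_um, q$intensity, xout = p$x_um[p$x_um >= 0.5],
                   rule = 1)$y) / 2
  expect_equal(got$intensity[!is.na(got$intensity)],
               ref[!is.na(ref)])
  far <- p; far$x_um <- far$x_um + 100
  expect_error(average_segments(p, far), "overlap")
})

test_that("group mean and SEM follow the sample-SD convention", {
  p1 <- data.frame(x_um = 1:5, intensity = rep(1, 5), n_pixels = 1)
  p3 <- data.frame(x_um = 1:5, intensity = rep(3, 5), n_pixels = 1)
  g <- group_mean_sem(list(p1, p3))
  expect_true(all(g$mean == 2))
  expect_true(all(g$sem == 1))             # SD = sqrt(2), SEM = 1
  gid <- group_mean_sem(list(p1, p1, p1))
  expect_true(all(gid$sem == 0))
  g1 <- group_mean_sem(list(p1))
  expect_true(all(is.na(g1$sem)))
  expect_true(all(g1$mean == 1))
})
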