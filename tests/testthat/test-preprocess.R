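# Preprocessing: inclination, strapdown integration, gravity removal,
# heading alignment, differentiation, gait-cycle detection, and the
# trial-level frame-recovery properties.

test_that("static inclination maps the measured gravity onto +z", {
  expect_equal(estimate_static_inclination(c(0, 0, 9.81)), diag(3),
               tolerance = 1e-12)
  R <- estimate_static_inclination(c(9.81, 0, 0))
  expect_equal(as.vector(R %*% c(9.81, 0, 0)), c(0, 0, 9.81), tolerance = 1e-9)
  v <- c(0, 6.937, 6.937)
  R <- estimate_static_inclination(v)
  expect_true(is_rotation(R, tol = 1e-9))
  expect_equal(as.vector(R %*% v), c(0, 0, sqrt(sum(v^2))), tolerance = 1e-9)
  expect_error(estimate_static_inclination(c(0, 0, 2)), "not static")
  expect_error(estimate_static_inclination(c(0, 0, 20)), "not static")
})

test_that("orientation integration matches the matrix-exponential closed form", {
  fs <- 120
  n <- fs + 1
  # 1 rad about z over 1 s
  gyr <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  R <- integrate_orientation(diag(3), gyr, fs)
  expect_lt(max(abs(R[, , n] - rotvec_to_rot(c(0, 0, 1)))), 1e-6)
  # 90 degrees about x over 1 s
  gyr <- matrix(rep(c(pi / 2, 0, 0), each = n), n, 3)
  R <- integrate_orientation(diag(3), gyr, fs)
  expect_lt(max(abs(R[, , n] - rotvec_to_rot(c(pi / 2, 0, 0)))), 1e-6)
  # zero rate: constant orientation
  R0 <- rotvec_to_rot(c(0.3, -0.2, 0.9))
  R <- integrate_orientation(R0, matrix(0, 10, 3), fs)
  expect_equal(R[, , 10], R0, tolerance = 1e-12)
  # every orientation in the series stays orthonormal
  set.seed(2)
  gyr <- matrix(stats::rnorm(3 * 600, sd = 2), 600, 3)
  R <- integrate_orientation(diag(3), gyr, fs)
  ortho <- vapply(seq_len(600), function(k) {
    max(abs(crossprod(R[, , k]) - diag(3)))
  }, numeric(1))
  expect_lt(max(ortho), 1e-9)
  expect_error(integrate_orientation(diag(3), matrix(NA_real_, 5, 3), fs),
               "non-finite")
})

test_that("gravity removal cancels gravity and integrates velocity", {
  fs <- 100
  n <- 201
  # arbitrary static orientation: levelled acceleration is zero
  R0 <- rotvec_to_rot(c(0.4, 0.3, -1.0))
  rec <- sensor_recording("s", acc = matrix(rep(t(R0) %*% c(0, 0, 9.81), n),
                                            n, 3, byrow = TRUE),
                          gyr = matrix(0, n, 3))
  lev <- level_and_remove_gravity(rec, integrate_orientation(R0, rec$gyr, fs),
                                  fs)
  expect_lt(max(abs(lev$acc)), 1e-9)
  # identity orientation: plain subtraction
  rec <- sensor_recording("s", acc = matrix(rep(c(1, 0, 9.81), 3), 3, 3,
                                            byrow = TRUE),
                          gyr = matrix(0, 3, 3))
  lev <- level_and_remove_gravity(rec,
                                  integrate_orientation(diag(3), rec$gyr, fs),
                                  fs)
  expect_equal(lev$acc[2, ], c(1, 0, 0), tolerance = 1e-12)
  # constant 0.1 m/s^2 for 2 s -> 0.2 m/s
  n <- 2 * fs + 1
  rec <- sensor_recording("s",
                          acc = matrix(rep(c(0.1, 0, 9.81), n), n, 3,
                                       byrow = TRUE),
                          gyr = matrix(0, n, 3))
  lev <- level_and_remove_gravity(rec,
                                  integrate_orientation(diag(3), rec$gyr, fs),
                                  fs)
  expect_equal(lev$vel[n, ], c(0.2, 0, 0), tolerance = 1e-9)
})

test_that("heading is the signed horizontal angle of the mean velocity", {
  cyc <- c(1, 10)
  vel <- matrix(rep(c(1.4, 0, 0.3), 10), 10, 3, byrow = TRUE)
  expect_equal(estimate_heading(vel, cyc), 0)
  vel <- matrix(rep(c(0, 1.4, 0.3), 10), 10, 3, byrow = TRUE)
  expect_equal(estimate_heading(vel, cyc), pi / 2)
  vel <- matrix(rep(c(1, -1, 0), 10), 10, 3, byrow = TRUE)
  th <- estimate_heading(vel, cyc)
  expect_equal(th, -pi / 4)
  # magnitude agrees with the unsigned arccos of the normalised dot product
  v <- c(1, -1)
  expect_equal(abs(th), acos(v[1] / sqrt(sum(v^2))))
  vel <- matrix(0, 10, 3)
  expect_error(estimate_heading(vel, cyc), "undefined")
})

test_that("heading rotation aligns velocity with +x and keeps z fixed", {
  lev <- list(acc = matrix(stats::rnorm(30), 10, 3),
              gyr = matrix(stats::rnorm(30), 10, 3),
              vel = matrix(rep(c(1, 1, 0.5), 10), 10, 3, byrow = TRUE))
  g0 <- apply_heading(lev, 0)
  expect_equal(g0$acc, lev$acc)
  th <- estimate_heading(lev$vel, c(1, 10))
  g <- apply_heading(lev, th)
  expect_equal(g$vel[1, ], c(sqrt(2), 0, 0.5), tolerance = 1e-12)
  expect_equal(g$acc[, 3], lev$acc[, 3])
  expect_equal(g$gyr[, 3], lev$gyr[, 3])
})

test_that("angular acceleration: exact on linear rates, bounded on sinusoids", {
  fs <- 120
  n <- 121
  t <- (0:(n - 1)) / fs
  gyr <- cbind(0, 0, t)
  a <- angular_acceleration(gyr, fs)
  expect_equal(a[2:(n - 1), 3], rep(1, n - 2), tolerance = 1e-9)
  expect_equal(a[2, 1:2], c(0, 0))
  # sinusoid: central-difference error <= h^2/6 * max|w'''| = (2*pi)^3/(6*120^2)
  gyr <- cbind(sin(2 * pi * t), 0, 0)
  a <- angular_acceleration(gyr, fs)
  expect_lt(max(abs(a[2:(n - 1), 1] - 2 * pi * cos(2 * pi * t[2:(n - 1)]))),
            (2 * pi)^3 / (6 * fs^2))
  expect_equal(angular_acceleration(matrix(1, 5, 3), fs), matrix(0, 5, 3))
  expect_error(angular_acceleration(matrix(0, 2, 3), fs), "3 samples")
})

test_that("cycle detection finds constructed stride boundaries", {
  fs <- 120
  t <- (0:round(8.3 * fs)) / fs
  # steps every 0.55 s: peaks of |sin| at T/4 + k*T/2 with T = 1.1 s
  s <- abs(sin(2 * pi / 1.1 * t)) + 0.05
  got <- detect_walking_cycles(s, fs)
  want <- round((1.1 / 4 + (0:7) * 1.1) * fs) + 1
  want <- want[want <= length(s)]
  expect_equal(length(got$boundaries), length(want))
  expect_true(all(abs(got$boundaries - want) <= 2))
  expect_error(detect_walking_cycles(rep(1, 960), fs), "no gait")
})

test_that("a simulated trial at default cadence spans about 6 s over 3 cycles", {
  tr <- simulate_trial(gait_params(seed = 21, noise_sigma_acc = 0,
                                   noise_sigma_gyr = 0))
  pre <- preprocess_trial(tr)
  expect_equal(pre$cycles$n_cycles, 3)
  # static standing prefix + gait initiation + 3 walking cycles: the used
  # recording is on the order of 6 s
  used_s <- pre$window[2] / tr$fs
  expect_gt(used_s, 5.5)
  expect_lt(used_s, 8)
  # the three analysed cycles themselves span 3 stride periods
  expect_equal((pre$window[2] - pre$window[1]) / tr$fs, 3 * 1.1,
               tolerance = 0.05)
})

test_that("gait frame is recovered on simulated walks with known heading", {
  for (seed in 1:4) {
    phi <- c(30, -120, 75, 170)[seed]
    tr <- fast_trial(seed = seed, heading_deg = phi)
    pre <- preprocess_trial(tr)
    w <- pre$window[1]:pre$window[2]
    errs <- vapply(pre$sensors, function(g) {
      v <- colMeans(g$vel[w, , drop = FALSE])
      abs(atan2(v[2], v[1])) * 180 / pi
    }, numeric(1))
    expect_lt(max(errs), 1)          # every sensor within 1 degree
  }
})

test_that("pipeline is equivariant to a common rotation of the raw data", {
  tr <- fast_trial(seed = 9)
  Q <- rot_z(1.1)
  tr2 <- tr
  tr2$sensors <- lapply(tr$sensors, function(s) {
    sensor_recording(s$sensor_id, s$acc %*% t(Q), s$gyr %*% t(Q))
  })
  p1 <- preprocess_trial(tr)
  p2 <- preprocess_trial(tr2)
  for (id in names(p1$sensors)) {
    expect_equal(p2$sensors[[id]]$acc, p1$sensors[[id]]$acc, tolerance = 1e-6)
    expect_equal(p2$sensors[[id]]$gyr, p1$sensors[[id]]$gyr, tolerance = 1e-6)
  }
})

test_that("static interval detection finds the quiet prefix", {
  tr <- fast_trial(seed = 13)
  truth <- attr(tr, "truth")
  det <- detect_static_interval(tr)
  expect_equal(det[1], 1L)
  # gait initiation ramps up smoothly (joint oscillations start ~0.4 stride
  # after the nominal onset), so the detected static end trails the onset by
  # the time the gyro first exceeds the threshold
  expect_gte(det[2], truth$onset - 2)
  expect_lte(det[2], truth$onset + round(0.6 * 1.1 * tr$fs))
})
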