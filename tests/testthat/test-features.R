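# Feature extraction: closed-form values, counts, ranking, transforms, and
# the trunk/limb correlation features for left-right disambiguation.

make_sig <- function(acc, gyr = NULL, angacc = NULL) {
  n <- nrow(acc)
  list(acc = acc,
       gyr = if (is.null(gyr)) matrix(stats::rnorm(3 * n), n, 3) else gyr,
       angacc = if (is.null(angacc)) matrix(stats::rnorm(3 * n), n, 3)
       else angacc)
}

test_that("RMS, variance and inter-axis correlations have their closed forms", {
  set.seed(1)
  n <- 1200
  t <- (0:(n - 1)) / 120
  # constant on one axis: RMS = |c|, Var = 0
  sig <- make_sig(matrix(rep(c(-3, 0.5, 2), n), n, 3, byrow = TRUE))
  f <- suppressWarnings(per_sensor_features(sig))
  expect_equal(unname(f["RMS_x_a"]), 3)
  expect_equal(unname(f["Var_x_a"]), 0)
  # sinusoid over whole cycles: RMS -> A/sqrt(2) within 1%
  A <- 2.5
  sig <- make_sig(cbind(A * sin(2 * pi * t), stats::rnorm(n), stats::rnorm(n)))
  f <- per_sensor_features(sig)
  expect_equal(unname(f["RMS_x_a"]), A / sqrt(2), tolerance = 0.01)
  # perfect linear dependence: inter-axis cc = 1
  x <- stats::rnorm(n)
  sig <- make_sig(cbind(x, 2 * x, stats::rnorm(n)))
  f <- per_sensor_features(sig)
  expect_equal(unname(f["IAC_xy_a"]), 1)
})

test_that("between-sensor correlations equal the brute-force pairwise oracle", {
  set.seed(4)
  n <- 240
  sigs <- lapply(1:3, function(i) {
    list(acc = matrix(stats::rnorm(3 * n), n, 3),
         gyr = matrix(stats::rnorm(3 * n), n, 3),
         angacc = matrix(stats::rnorm(3 * n), n, 3))
  })
  names(sigs) <- paste0("s", 1:3)
  X <- cross_sensor_features(sigs)
  # oracle: explicit pairwise correlations of the x-component of acceleration
  ax <- sapply(sigs, function(g) g$acc[, 1])
  for (i in 1:3) {
    ccs <- sapply(setdiff(1:3, i), function(j) stats::cor(ax[, i], ax[, j]))
    expect_equal(unname(X[i, "SumCC_x_a"]), sum(ccs), tolerance = 1e-12)
    expect_equal(unname(X[i, "MaxCC_x_a"]), max(ccs), tolerance = 1e-12)
  }
  # a duplicated sensor has MaxCC = 1 on every component
  sigs$s3 <- sigs$s1
  X <- cross_sensor_features(sigs)
  expect_true(all(abs(X[1, grep("^MaxCC", colnames(X))] - 1) < 1e-12))
  expect_error(cross_sensor_features(sigs[1]), ">= 2 sensors")
})

test_that("feature counts: 57 ranked/normalized, 33 raw, 45 for step 2", {
  expect_equal(count_features("rank"), 57)
  expect_equal(count_features("normalize"), 57)
  expect_equal(count_features("raw"), 33)
  n <- 120
  sig <- make_sig(matrix(stats::rnorm(3 * n), n, 3))
  trunk <- matrix(stats::rnorm(3 * n), n, 3)
  expect_length(step2_features(sig, trunk, 120), 45)
})

test_that("fractional ranking follows the 1 2.5 2.5 4 convention", {
  expect_equal(fractional_rank(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(fractional_rank(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(fractional_rank(rep(7, 4)), rep(2.5, 4))
  n <- 17
  set.seed(2)
  for (i in 1:20) {
    v <- sample(1:9, n, replace = TRUE) + stats::rnorm(n, sd = 0.01)
    r <- fractional_rank(v)
    expect_equal(sum(r), n * (n + 1) / 2)              # rank conservation
    expect_equal(fractional_rank(r), r)                # idempotence
    expect_equal(fractional_rank(exp(v)), r)           # monotone invariance
  }
  expect_error(fractional_rank(c(1, NA, 2)), "non-finite")
})

test_that("table transforms: per-trial ranks, z-scores, raw column drop", {
  tr1 <- fast_trial(seed = 31)
  tr2 <- fast_trial(seed = 32)
  tab <- rbind(extract_features(preprocess_trial(tr1)),
               extract_features(preprocess_trial(tr2)))
  expect_equal(ncol(tab) - 3, 57)
  rk <- transform_table(tab, "rank")
  n <- 17
  for (tid in unique(rk$trial_id)) {
    cols <- rk[rk$trial_id == tid, feature_registry("rank")]
    expect_true(all(abs(colSums(cols) - n * (n + 1) / 2) < 1e-9))
  }
  nm <- transform_table(tab, "normalize")
  cols <- nm[nm$trial_id == tr1$trial_id, feature_registry("rank")]
  expect_true(all(abs(colMeans(cols)) < 1e-9))
  expect_true(all(abs(apply(cols, 2, stats::sd) - 1) < 1e-9))
  raw <- transform_table(tab, "raw")
  expect_equal(sum(grepl("^(SumCC|MaxCC)_", names(raw))), 0)
  expect_equal(length(feature_columns(raw)), 33)
})

test_that("rank transform is invariant to per-trial rescaling, raw is not", {
  tr <- fast_trial(seed = 33)
  tab <- extract_features(preprocess_trial(tr))
  tab2 <- tab
  fc <- feature_registry("rank")
  tab2[, fc] <- tab2[, fc] * 3.7          # e.g. a unit change
  expect_equal(transform_table(tab2, "rank")[, fc],
               transform_table(tab, "rank")[, fc])
  expect_false(isTRUE(all.equal(transform_table(tab2, "raw")[, feature_registry("raw")],
                                transform_table(tab, "raw")[, feature_registry("raw")])))
})

test_that("trunk orientation integrates and detrends angular velocity", {
  fs <- 120
  n <- 6 * fs
  t <- (0:(n - 1)) / fs
  # zero rate -> zero angle; constant rate -> pure ramp, detrended to ~0
  th <- trunk_orientation(matrix(0, n, 3), fs)
  expect_lt(max(abs(th)), 1e-12)
  th <- trunk_orientation(matrix(rep(c(0.3, 0, 0), n), n, 3, byrow = TRUE), fs)
  expect_lt(max(abs(th)), 1e-9)
  # sinusoidal rate: amplitude A/(2*pi*f) within 1%
  A <- 0.4; f <- 1
  th <- trunk_orientation(cbind(A * sin(2 * pi * f * t), 0, 0), fs)
  expect_equal(max(abs(th[, 1])), A / (2 * pi * f), tolerance = 0.01)
  # best-fit linear trend is removed
  fit <- stats::lm.fit(cbind(1, t), th[, 1])
  expect_lt(abs(fit$coefficients[2]), 1e-9)
})

test_that("limb-trunk correlations: proportional series give cc 1, null stays small", {
  set.seed(8)
  n <- 720
  fs <- 120
  trunk <- matrix(stats::rnorm(3 * n), n, 3)
  sig <- make_sig(cbind(stats::rnorm(n), stats::rnorm(n), 2 * trunk[, 1]))
  cc <- step2_features(sig, trunk, fs)
  expect_equal(unname(cc["cc_az_thetax"]), 1, tolerance = 1e-12)
  # independent series: |cc| < 0.3 for at least 95% of random runs
  hits <- replicate(40, {
    s <- make_sig(matrix(stats::rnorm(3 * n), n, 3))
    max(abs(step2_features(s, matrix(stats::rnorm(3 * n), n, 3), fs)))
  })
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("left/right chaining uses the prescribed acceleration components", {
  set.seed(9)
  n <- 300
  mk <- function(acc) list(acc = acc, gyr = matrix(stats::rnorm(3 * n), n, 3),
                           angacc = matrix(stats::rnorm(3 * n), n, 3))
  left_ax <- stats::rnorm(n)
  right_ax <- stats::rnorm(n)
  neighbors <- list(left = mk(cbind(left_ax, 0.1, 0.2)),
                    right = mk(cbind(right_ax, 0.1, 0.2)))
  # a foot candidate sharing the LEFT lower leg's a_x must correlate 1 left
  cands <- list(c1 = mk(cbind(left_ax, stats::rnorm(n), stats::rnorm(n))),
                c2 = mk(cbind(right_ax, stats::rnorm(n), stats::rnorm(n))))
  M <- suppressWarnings(step3_features(cands, neighbors, "foot"))
  expect_equal(unname(M["c1", "left"]), 1, tolerance = 1e-12)
  expect_equal(unname(M["c2", "right"]), 1, tolerance = 1e-12)
  # feet chain over a_x: permuting y/z must not change the result
  cands2 <- lapply(cands, function(s) {
    s$acc <- s$acc[, c(1, 3, 2)]
    s
  })
  M2 <- suppressWarnings(step3_features(cands2, neighbors, "foot"))
  expect_equal(M2, M)
  # hands chain over a_y
  candy <- list(c1 = mk(cbind(stats::rnorm(n), left_ax, stats::rnorm(n))),
                c2 = mk(cbind(stats::rnorm(n), right_ax, stats::rnorm(n))))
  My <- suppressWarnings(step3_features(candy, neighbors_y <- list(
    left = mk(cbind(0.1, left_ax, 0.2)), right = mk(cbind(0.1, right_ax, 0.2))
  ), "hand"))
  expect_equal(unname(My["c1", "left"]), 1, tolerance = 1e-12)
  expect_error(step3_features(cands, list(left = neighbors$left), "foot"),
               "resolved")
  expect_error(step3_features(cands, neighbors, "pelvis"), "no left/right")
})

test_that("zero-variance correlations map to 0 with a warning", {
  n <- 50
  sig <- list(acc = matrix(1, n, 3), gyr = matrix(1, n, 3),
              angacc = matrix(1, n, 3))
  w <- testthat::capture_warnings(f <- per_sensor_features(sig))
  expect_true(all(grepl("zero-variance", w)) && length(w) > 0)
  expect_equal(unname(f["IAC_xy_a"]), 0)
})

test_that("features barely move under a whole-cycle time shift", {
  # steady-state windows (gait initiation excluded): shifting the analysis
  # window by one full stride leaves the features essentially unchanged
  p <- fast_params(seed = 77, n_cycles = 6)
  tr <- simulate_trial(p)
  pre <- preprocess_trial(tr, n_cycles = 3)
  b <- pre$cycles$boundaries
  len <- b[5] - b[2]
  preA <- pre
  preA$window <- c(b[2], b[2] + len)
  preB <- pre
  preB$window <- c(b[3], b[3] + len)
  fA <- extract_features(preA)
  fB <- extract_features(preB)
  fc <- feature_registry("rank")
  A <- as.matrix(fA[, fc])
  B <- as.matrix(fB[, fc])
  # relative change with a per-feature floor of 5% of the feature's scale
  # across sensors (correlation sums can nearly cancel on single sensors)
  floor_ <- matrix(0.05 * pmax(apply(abs(A), 2, max), 1e-3),
                   nrow(A), ncol(A), byrow = TRUE)
  rel <- abs(B - A) / pmax(abs(A), floor_)
  expect_lt(stats::median(rel), 0.01)
  expect_lt(max(rel), 0.1)
})
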