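# Preprocessing: sensor-frame signals -> gait-aligned global frame.
#
# Per sensor: (1) inclination from the static-standing accelerometer mean,
# (2) strapdown gyroscope integration of the orientation, (3) rotation of the
# signals into the levelled frame and gravity removal, (4) trapezoidal
# velocity integration, (5) heading alignment using the mean velocity of the
# first full walking cycle, (6) angular acceleration by numerical
# differentiation. Trial-level: gait-cycle detection from the summed signal
# magnitudes of all sensors.

#' Inclination from the static accelerometer mean
#'
#' While standing still the accelerometer measures only gravity, so the mean
#' static reading fixes the sensor tilt. Returns the shortest-arc rotation
#' mapping the mean onto the vertical; the heading (yaw) component is left
#' arbitrary and resolved later from the walking direction.
#'
#' @param static_acc_mean 3-vector, mean accelerometer output over the static
#'   interval, m/s^2
#' @return 3x3 rotation matrix `R` with `R %*% static_acc_mean` along +z
#' @export
estimate_static_inclination <- function(static_acc_mean) {
  nrm <- sqrt(sum(static_acc_mean^2))
  if (nrm < 0.5 * GRAVITY || nrm > 1.5 * GRAVITY) {
    stop("sensor not static or miscalibrated: |mean acc| = ",
         format(nrm, digits = 4), " m/s^2")
  }
  rotation_between(static_acc_mean, c(0, 0, 1))
}

#' Strapdown orientation integration
#'
#' Propagates the sensor-to-levelled-frame rotation through the gyroscope
#' signal by per-sample axis-angle increments,
#' `R[t+1] = R[t] %*% expm(skew(gyr[t]) / fs)`, which is exact when the
#' angular velocity is constant over a sample. Orientations are
#' re-orthonormalised periodically.
#'
#' @param R0 initial 3x3 rotation (from [estimate_static_inclination()])
#' @param gyr N x 3 angular velocity, rad/s, sensor frame
#' @param fs sampling frequency, Hz
#' @return 3 x 3 x N array of rotations
#' @export
integrate_orientation <- function(R0, gyr, fs) {
  if (fs <= 0) stop("fs must be positive")
  if (!is_rotation(R0, tol = 1e-6)) stop("R0 is not a rotation matrix")
  gyr <- as.matrix(gyr)
  if (any(!is.finite(gyr))) stop("non-finite gyroscope samples")
  n <- nrow(gyr)
  out <- array(0, dim = c(3, 3, n))
  inc <- rotvec_to_rot_batch(gyr[-n, , drop = FALSE] / fs)
  R <- R0
  out[, , 1] <- R
  for (k in seq_len(n - 1)) {
    R <- R %*% inc[, , k]
    if (k %% 256 == 0) R <- orthonormalize(R)
    out[, , k + 1] <- R
  }
  out[, , n] <- orthonormalize(out[, , n])
  out
}

#' Rotate signals to the levelled frame and remove gravity
#'
#' `acc[t] = R[t] %*% s[t] + g` with `g = (0, 0, -9.81)`: a resting
#' accelerometer reads +9.81 on the up-axis, so the levelled free
#' acceleration is zero at rest. Velocity is the trapezoidal integral of the
#' free acceleration from rest.
#'
#' @param rec a [sensor_recording()]
#' @param R_series 3 x 3 x N rotation array from [integrate_orientation()]
#' @param fs sampling frequency, Hz
#' @return list with `acc`, `gyr`, `vel` (N x 3 matrices) and `gravity_const`
#' @export
level_and_remove_gravity <- function(rec, R_series, fs) {
  n <- nrow(rec$acc)
  if (dim(R_series)[3] != n) stop("rotation series length mismatch")
  g <- c(0, 0, -GRAVITY)
  acc <- rot_batch_apply(R_series, rec$acc)
  acc <- sweep(acc, 2, -g)    # acc + g
  gyr <- rot_batch_apply(R_series, rec$gyr)
  vel <- apply(acc, 2, pracma::cumtrapz) / fs
  list(acc = acc, gyr = gyr, vel = vel, gravity_const = g)
}

#' Heading of the walking direction from the first-cycle mean velocity
#'
#' Returns the signed angle in the horizontal plane between the +x axis of
#' the levelled frame and the mean velocity over the first full walking
#' cycle. The magnitude equals the arccos of the normalised dot product with
#' +x; the sign is taken from the y-component (a two-argument arctangent),
#' since an unsigned angle cannot distinguish leftward from rightward
#' heading.
#'
#' @param vel N x 3 levelled velocity, m/s
#' @param first_cycle integer `c(start, end)`, 1-based inclusive sample range
#'   of the first full walking cycle
#' @return heading angle theta, radians, in (-pi, pi]
#' @export
estimate_heading <- function(vel, first_cycle) {
  i <- first_cycle[1]:first_cycle[2]
  if (first_cycle[1] < 1 || first_cycle[2] > nrow(vel)) {
    stop("first cycle outside the velocity series")
  }
  v <- colMeans(vel[i, , drop = FALSE])
  if (sqrt(v[1]^2 + v[2]^2) < 0.1) {
    stop("walking direction undefined: mean horizontal speed < 0.1 m/s")
  }
  atan2(v[2], v[1])
}

#' Rotate levelled signals into the gait frame
#'
#' Applies the heading rotation about the vertical axis so that the walking
#' direction maps onto +x (y then points left, z is unchanged).
#'
#' @param leveled list from [level_and_remove_gravity()]
#' @param theta heading from [estimate_heading()], radians
#' @return list with `acc`, `gyr`, `vel` in the gait frame and `heading`
#' @export
apply_heading <- function(leveled, theta) {
  if (!is.finite(theta)) stop("non-finite heading angle")
  Rz <- rot_z(-theta)
  list(acc = leveled$acc %*% t(Rz),
       gyr = leveled$gyr %*% t(Rz),
       vel = leveled$vel %*% t(Rz),
       heading = theta)
}

#' Angular acceleration by numerical differentiation
#'
#' Central differences at interior samples, one-sided differences at the two
#' ends.
#'
#' @param gyr N x 3 angular velocity, rad/s
#' @param fs sampling frequency, Hz
#' @return N x 3 angular acceleration, rad/s^2
#' @export
angular_acceleration <- function(gyr, fs) {
  gyr <- as.matrix(gyr)
  n <- nrow(gyr)
  if (n < 3) stop("need at least 3 samples to differentiate")
  out <- matrix(0, n, 3)
  out[2:(n - 1), ] <- (gyr[3:n, ] - gyr[1:(n - 2), ]) * (fs / 2)
  out[1, ] <- (gyr[2, ] - gyr[1, ]) * fs
  out[n, ] <- (gyr[n, ] - gyr[n - 1, ]) * fs
  out
}

#' Detect walking (stride) cycles from the trial summary signal
#'
#' The summary signal is the sum over sensors of the acceleration and
#' angular-velocity magnitudes. Peaks correspond to steps; a stride spans two
#' successive same-foot contacts, so stride boundaries are every second
#' accepted peak. Peaks must be at least `min_distance` seconds apart and
#' rise above `median + height_frac * (p95 - median)` of the summary.
#'
#' The summary is smoothed with a centred moving average (`smooth_s` seconds)
#' before peak picking, since acceleration and angular-velocity magnitudes
#' peak at different phases of a step and would otherwise each contribute a
#' hump.
#'
#' @param summary numeric vector, summed magnitudes
#' @param fs sampling frequency, Hz
#' @param min_distance minimum peak separation, s
#' @param height_frac height threshold as a fraction of the p95-median spread
#' @param smooth_s moving-average length, s (0 disables smoothing)
#' @return list with `boundaries` (sample indices of stride starts),
#'   `n_cycles`, and `peaks` (all accepted step peaks)
#' @export
detect_walking_cycles <- function(summary, fs, min_distance = 0.4,
                                  height_frac = 0.5, smooth_s = 0.3) {
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s * fs))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && length(summary) > k) {
      sm <- as.numeric(stats::filter(summary, rep(1 / k, k), sides = 2))
      half <- (k - 1L) / 2L
      sm[seq_len(half)] <- sm[half + 1L]
      n <- length(sm)
      sm[(n - half + 1L):n] <- sm[n - half]
      summary <- sm
    }
  }
  med <- stats::median(summary)
  p95 <- stats::quantile(summary, 0.95, names = FALSE)
  if (p95 - med < 1e-9) stop("no gait detected: summary signal has no peaks")
  thr <- med + height_frac * (p95 - med)
  pk <- pracma::findpeaks(summary, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_distance * fs)))
  if (is.null(pk) || nrow(pk) < 2) stop("no gait detected: < 2 accepted peaks")
  idx <- sort(pk[, 2])
  boundaries <- idx[seq(1, length(idx), by = 2)]
  if (length(boundaries) < 2) stop("no gait detected: < 1 full stride")
  list(boundaries = boundaries, n_cycles = length(boundaries) - 1, peaks = idx)
}

#' Auto-detect the static standing interval
#'
#' Longest prefix window of at least `min_duration` seconds during which the
#' gyroscope magnitude stays below `gyr_thresh` on every sensor.
#'
#' @param trial an [imu_trial()]
#' @param gyr_thresh rad/s threshold (default 0.1)
#' @param min_duration minimum static duration, s
#' @return integer `c(start, end)`, 1-based inclusive
#' @export
detect_static_interval <- function(trial, gyr_thresh = 0.1, min_duration = 1) {
  mags <- sapply(trial$sensors, function(s) sqrt(rowSums(s$gyr^2)))
  quiet <- apply(mags, 1, max) < gyr_thresh
  end <- if (!quiet[1]) 0L else if (all(quiet)) length(quiet) else
    which(!quiet)[1] - 1L
  if (end < ceiling(min_duration * trial$fs)) {
    stop("no static prefix of >= ", min_duration, " s found")
  }
  c(1L, end)
}

#' Preprocess a trial into gait-frame signals and gait cycles
#'
#' Runs the full per-sensor chain (inclination, strapdown integration,
#' levelling, velocity, heading alignment, angular acceleration) and the
#' trial-level gait-cycle detection. Heading is estimated per sensor from its
#' own first-cycle mean velocity (`heading_mode = "per_sensor"`, the
#' default), which tolerates arbitrary mounting yaw; `"common"` applies the
#' circular-median heading of all sensors to every sensor and assumes the
#' mountings share their yaw.
#'
#' @param trial an [imu_trial()]
#' @param n_cycles number of walking cycles to keep for analysis (1-3)
#' @param heading_mode `"per_sensor"` or `"common"`
#' @param heading_noise_sd optional perturbation: sd (radians) of Gaussian
#'   noise added to each sensor's heading angle (sensitivity analyses)
#' @param acc_bias optional perturbation: either a single magnitude (m/s^2,
#'   applied along a random direction per sensor) or a named list of 3-vectors
#'   per sensor, added to the raw accelerometer signal
#' @return object of class `preprocessed_trial`: per-sensor gait-frame
#'   signals (`acc`, `gyr`, `angacc`, `vel`, `heading`), the detected
#'   `cycles`, the analysis `window` (sample range spanning the first
#'   `n_cycles` cycles), and the trial metadata
#' @export
preprocess_trial <- function(trial, n_cycles = 3,
                             heading_mode = c("per_sensor", "common"),
                             heading_noise_sd = 0, acc_bias = NULL) {
  heading_mode <- match.arg(heading_mode)
  si <- trial$static_interval
  fs <- trial$fs

  leveled <- lapply(trial$sensors, function(s) {
    acc <- s$acc
    if (!is.null(acc_bias)) {
      b <- if (is.list(acc_bias)) acc_bias[[s$sensor_id]] else {
        u <- stats::rnorm(3)
        u / sqrt(sum(u^2)) * acc_bias
      }
      acc <- sweep(acc, 2, -b)
    }
    rec <- s
    rec$acc <- acc
    R0 <- estimate_static_inclination(colMeans(acc[si[1]:si[2], , drop = FALSE]))
    Rser <- integrate_orientation(R0, s$gyr, fs)
    level_and_remove_gravity(rec, Rser, fs)
  })

  summary <- Reduce(`+`, lapply(leveled, function(l) {
    sqrt(rowSums(l$acc^2)) + sqrt(rowSums(l$gyr^2))
  }))
  cycles <- detect_walking_cycles(summary, fs)

  first_cycle <- c(cycles$boundaries[1], cycles$boundaries[2])
  thetas <- vapply(leveled, function(l) estimate_heading(l$vel, first_cycle),
                   numeric(1))
  if (heading_noise_sd > 0) {
    thetas <- thetas + stats::rnorm(length(thetas), sd = heading_noise_sd)
  }
  if (heading_mode == "common") {
    thetas[] <- circular_median(thetas)
  }

  sensors <- Map(function(l, th) {
    g <- apply_heading(l, th)
    g$angacc <- angular_acceleration(g$gyr, fs)
    g
  }, leveled, thetas)

  k <- min(n_cycles, cycles$n_cycles)
  if (k < n_cycles) {
    warning("only ", cycles$n_cycles, " cycles detected; using ", k)
  }
  window <- c(cycles$boundaries[1], cycles$boundaries[1 + k])

  structure(
    list(sensors = sensors, cycles = cycles, window = window,
         n_cycles_used = k, fs = fs, labels = trial$labels,
         config = trial$config, trial_id = trial$trial_id),
    class = "preprocessed_trial"
  )
}
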