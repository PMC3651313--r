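# Synthetic gait-IMU simulator. Generates labelled walking trials with the
# statistical structure the identification method exploits: a static standing
# prefix; periodic walking at ~5 km/h with a ~1.1 s stride; larger
# acceleration RMS on leg sensors than arm/trunk sensors (with a fixed
# ordering of per-class signal energy); left-right anti-phase limb motion
# (stride-frequency terms flip sign between sides, step-frequency terms do
# not); pelvis and sternum roll phase-locked to the ipsilateral limb swing
# with the sign that makes the right limb's vertical acceleration correlate
# positively with trunk roll; chains of shared stride-frequency components
# between adjacent segments on the same side; arbitrary per-sensor mounting
# rotations; accelerometer bias and white noise.
#
# Signals are specified in the walking frame (x = walking direction,
# y = left, z = up) as sums of sinusoids at the stride frequency f0 and step
# frequency 2*f0. Velocities are designed directly (so the mean first-cycle
# velocity points along the heading) and differentiated analytically to get
# free accelerations; segment orientations are small oscillating rotation
# vectors, and gyroscope outputs are derived from exact orientation
# increments so that strapdown integration reproduces the simulated
# orientation.

# Per-class oscillation terms, frozen. Columns: axis (1=x, 2=y, 3=z),
# amp (acc: m/s^2 peak; rot: rad peak), mult (1 = stride frequency,
# 2 = step frequency), sided (1: phase shifts by mult*pi on the left side),
# phase (rad), arm (1: scaled by arm_swing_amplitude),
# troll (1: scaled by pelvis_roll_amplitude).
.term <- function(axis, amp, mult, sided = 0, phase = 0, arm = 0, troll = 0) {
  c(axis = axis, amp = amp, mult = mult, sided = sided, phase = phase,
    arm = arm, troll = troll)
}

SEGMENT_DYNAMICS <- list(
  pelvis = list(
    acc = list(.term(1, 0.5, 2, phase = 0.4), .term(2, 0.3, 2, phase = 1.0),
               .term(3, 1.2, 2)),
    rot = list(.term(1, 0.07, 1, troll = 1), .term(2, 0.02, 2, phase = 0.5),
               .term(3, 0.03, 1, phase = 1.2))
  ),
  sternum = list(
    acc = list(.term(1, 0.4, 2, phase = 0.4), .term(2, 0.2, 2, phase = 1.0),
               .term(3, 1.0, 2)),
    rot = list(.term(1, 0.05, 1, troll = 1), .term(2, 0.015, 2, phase = 0.5),
               .term(3, 0.02, 1, phase = 1.2))
  ),
  head = list(
    acc = list(.term(1, 0.3, 2, phase = 0.4), .term(2, 0.15, 2, phase = 1.0),
               .term(3, 0.8, 2)),
    rot = list(.term(1, 0.02, 1), .term(2, 0.01, 2, phase = 0.5),
               .term(3, 0.01, 1, phase = 1.2))
  ),
  shoulder = list(
    acc = list(.term(1, 0.6, 2, phase = 0.4), .term(2, 0.3, 2, phase = 1.0),
               .term(3, 1.2, 2), .term(3, 0.9, 1, sided = 1, arm = 1)),
    rot = list(.term(2, 0.06, 1, sided = 1, arm = 1),
               .term(1, 0.02, 1, phase = 0.7))
  ),
  upper_arm = list(
    acc = list(.term(1, 0.6, 2, phase = 0.4),
               .term(1, 1.5, 1, sided = 1, arm = 1),
               .term(2, 0.3, 2, phase = 1.0), .term(3, 1.3, 2),
               .term(3, 1.4, 1, sided = 1, arm = 1)),
    rot = list(.term(2, 0.25, 1, sided = 1, arm = 1),
               .term(3, 0.03, 1, phase = 1.2))
  ),
  forearm = list(
    acc = list(.term(1, 0.6, 2, phase = 0.4),
               .term(1, 2.6, 1, sided = 1, arm = 1),
               .term(2, 0.3, 2, phase = 1.0),
               .term(2, 1.2, 1, sided = 1, arm = 1), .term(3, 1.8, 2)),
    rot = list(.term(2, 0.35, 1, sided = 1, arm = 1),
               .term(1, 0.05, 1, sided = 1, phase = 0.6, arm = 1))
  ),
  hand = list(
    acc = list(.term(1, 0.6, 2, phase = 0.4),
               .term(1, 2.9, 1, sided = 1, arm = 1),
               .term(2, 0.3, 2, phase = 1.0),
               .term(2, 1.8, 1, sided = 1, arm = 1), .term(3, 2.0, 2)),
    rot = list(.term(2, 0.40, 1, sided = 1, arm = 1),
               .term(3, 0.06, 1, sided = 1, phase = 0.8, arm = 1))
  ),
  upper_leg = list(
    acc = list(.term(1, 0.8, 2, phase = 0.4), .term(1, 4.0, 1, sided = 1),
               .term(2, 0.4, 2, phase = 1.0), .term(3, 2.0, 2),
               .term(3, 2.8, 1, sided = 1)),
    rot = list(.term(2, 0.35, 1, sided = 1), .term(1, 0.04, 1, phase = 0.9))
  ),
  lower_leg = list(
    acc = list(.term(1, 0.8, 2, phase = 0.4), .term(1, 5.5, 1, sided = 1),
               .term(2, 0.4, 2, phase = 1.0), .term(3, 2.6, 2)),
    rot = list(.term(2, 0.55, 1, sided = 1),
               .term(1, 0.04, 1, sided = 1, phase = 0.5))
  ),
  foot = list(
    acc = list(.term(1, 0.8, 2, phase = 0.4), .term(1, 8.0, 1, sided = 1),
               .term(2, 0.5, 2, phase = 1.0), .term(3, 3.5, 2)),
    rot = list(.term(2, 0.45, 1, sided = 1),
               .term(2, 0.15, 2, sided = 1, phase = 0.7),
               .term(3, 0.06, 1, sided = 1, phase = 1.0))
  )
)

#' Gait simulation parameters
#'
#' Defaults represent a healthy adult walking at normal speed: 1.39 m/s
#' (~5 km/h), 1.1 s stride period, 3 walking cycles after 3 s of quiet
#' standing, sampled at 120 Hz. `arm_swing_amplitude` and
#' `pelvis_roll_amplitude` scale the arm and trunk-roll oscillations
#' (0 suppresses them; 0 arm swing reproduces a subject whose arms barely
#' move). Noise defaults are typical MEMS magnitudes; `acc_bias` (m/s^2) is
#' applied along a random per-sensor direction.
#'
#' @param walking_speed m/s
#' @param stride_period s
#' @param n_cycles number of walking (stride) cycles
#' @param static_duration s of quiet standing before walking
#' @param fs sampling frequency, Hz
#' @param arm_swing_amplitude scale factor for arm oscillations
#' @param pelvis_roll_amplitude scale factor for pelvis/sternum roll
#' @param noise_sigma_acc accelerometer white-noise sd, m/s^2
#' @param noise_sigma_gyr gyroscope white-noise sd, rad/s
#' @param acc_bias accelerometer bias magnitude, m/s^2
#' @param heading_deg walking direction, degrees from the +x axis
#' @param mounting `"random"` (uniform 3D rotations), `"well_mounted"`
#'   (~5 degree misalignments), or `"aligned"`
#' @param config a [sensor_config()] (or its name)
#' @param amp_scale global amplitude scale (trial-level jitter hook)
#' @param sensor_amp_jitter half-width of the uniform per-sensor relative
#'   amplitude jitter
#' @param seed optional integer seed (trial is deterministic given the seed)
#' @return list of validated parameters, class `gait_params`
#' @export
gait_params <- function(walking_speed = 1.39, stride_period = 1.1,
                        n_cycles = 3, static_duration = 3, fs = 120,
                        arm_swing_amplitude = 1, pelvis_roll_amplitude = 1,
                        noise_sigma_acc = 0.02, noise_sigma_gyr = 0.002,
                        acc_bias = 0, heading_deg = 0,
                        mounting = c("random", "well_mounted", "aligned"),
                        config = "full_body", amp_scale = 1,
                        sensor_amp_jitter = 0.03, seed = NULL) {
  mounting <- match.arg(mounting)
  if (is.character(config)) config <- sensor_config(config)
  stopifnot(fs >= 20, n_cycles >= 1, walking_speed > 0, stride_period > 0,
            arm_swing_amplitude >= 0, pelvis_roll_amplitude >= 0,
            noise_sigma_acc >= 0, noise_sigma_gyr >= 0, acc_bias >= 0,
            static_duration >= 1)
  structure(as.list(environment()), class = "gait_params")
}

# smooth 0->1 onset envelope (half-cosine over tau seconds)
.envelope <- function(tw, tau) {
  e <- ifelse(tw <= 0, 0, ifelse(tw >= tau, 1, 0.5 * (1 - cos(pi * tw / tau))))
  de <- ifelse(tw <= 0 | tw >= tau, 0, 0.5 * pi / tau * sin(pi * tw / tau))
  list(e = e, de = de)
}

# evaluate one segment's walking-frame free acceleration (N x 3) and
# orientation rotation vector (N x 3) for side "none"/"left"/"right"
.segment_signals <- function(class, side, tw, env, p, f0, amp) {
  dyn <- SEGMENT_DYNAMICS[[class]]
  N <- length(tw)
  acc <- matrix(0, N, 3)
  rot <- matrix(0, N, 3)
  for (tm in dyn$acc) {
    A <- amp * tm[["amp"]] *
      (if (tm[["arm"]]) p$arm_swing_amplitude else 1)
    if (A == 0) next
    om <- 2 * pi * f0 * tm[["mult"]]
    ph <- tm[["phase"]] + if (tm[["sided"]] && side == "left")
      tm[["mult"]] * pi else 0
    # velocity-designed term: v = (A/om) e (-cos), a = dv/dt
    acc[, tm[["axis"]]] <- acc[, tm[["axis"]]] +
      A * env$e * sin(om * tw + ph) -
      (A / om) * env$de * cos(om * tw + ph)
  }
  for (tm in dyn$rot) {
    A <- amp * tm[["amp"]] *
      (if (tm[["arm"]]) p$arm_swing_amplitude else 1) *
      (if (tm[["troll"]]) p$pelvis_roll_amplitude else 1)
    if (A == 0) next
    om <- 2 * pi * f0 * tm[["mult"]]
    ph <- tm[["phase"]] + if (tm[["sided"]] && side == "left")
      tm[["mult"]] * pi else 0
    rot[, tm[["axis"]]] <- rot[, tm[["axis"]]] + A * env$e * sin(om * tw + ph)
  }
  list(acc = acc, rot = rot)
}

#' Simulate one labelled walking trial
#'
#' @param params a [gait_params()]
#' @param trial_id identifier for the trial
#' @return an [imu_trial()] with ground-truth `labels`; attribute `truth`
#'   holds the heading (deg), the constructed stride-cycle boundary sample
#'   indices, the onset sample, and the parameters
#' @export
simulate_trial <- function(params = gait_params(), trial_id = "sim") {
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  fs <- p$fs
  f0 <- 1 / p$stride_period
  onset <- floor(p$static_duration * fs) + 1L
  # gait initiation: the forward-speed ramp spans the first 1.5 strides and
  # the joint-oscillation envelope switches on during [0.75, 1] stride, so
  # the initiation transients stay below the cycle detector's acceptance
  # threshold and every gait cycle from the first accepted step peak onwards
  # is in steady state (the residual speed ramp acts along x only)
  dur <- p$static_duration + p$stride_period * (p$n_cycles + 1.6) + 0.3
  N <- floor(dur * fs) + 1L
  t <- (seq_len(N) - 1) / fs
  tw <- t - p$static_duration              # time since walking onset
  env <- .envelope(tw - 0.375 * p$stride_period, 0.625 * p$stride_period)

  # common forward velocity ramp: v = v0 * r(tw), a = v0 * r'(tw)
  ramp <- .envelope(tw, 1.5 * p$stride_period)
  acc_common <- cbind(p$walking_speed * ramp$de, 0, 0)

  segments <- p$config$segments
  ids <- sprintf("S%02d", seq_along(segments))
  assign_order <- sample(seq_along(segments))   # sensor ids don't leak labels
  labels <- stats::setNames(segments[assign_order], ids)

  Rz_head <- rot_z(p$heading_deg * pi / 180)
  g_up <- c(0, 0, GRAVITY)

  sensors <- vector("list", length(ids))
  summary_nf <- numeric(N)   # noise-free summed magnitudes (ground truth)
  for (si in seq_along(ids)) {
    seg <- labels[[ids[si]]]
    cls <- segment_class(seg)
    side <- segment_side(seg)
    amp <- p$amp_scale *
      (1 + stats::runif(1, -p$sensor_amp_jitter, p$sensor_amp_jitter))
    sig <- .segment_signals(cls, side, tw, env, p, f0, amp)
    acc_w <- sig$acc + acc_common

    R_mount <- switch(p$mounting,
      random = random_rotation(),
      well_mounted = rotvec_to_rot(stats::rnorm(3, sd = 5 * pi / 180)),
      aligned = diag(3)
    )
    E <- rotvec_to_rot_batch(sig$rot)               # segment orientation
    Rsg <- rot_batch_multiply(Rz_head, E)           # segment -> global
    R <- rot_batch_multiply(Rsg, R_mount)           # sensor -> global

    # specific force in sensor frame: f = R' (a_g + g_up)
    a_g <- acc_w %*% t(Rz_head)
    f_s <- rot_batch_apply(R, sweep(a_g, 2, -g_up), transpose = TRUE)

    # gyroscope from exact orientation increments (mounting cancels heading)
    Et <- rot_batch_transpose(E[, , -N, drop = FALSE])
    M <- rot_batch_multiply(Et, E[, , -1, drop = FALSE])
    M <- rot_batch_multiply(rot_batch_multiply(t(R_mount), M), R_mount)
    w_s <- rot_to_rotvec_batch(M) * fs
    w_s <- rbind(w_s, w_s[N - 1, ])
    summary_nf <- summary_nf + sqrt(rowSums(acc_w^2)) + sqrt(rowSums(w_s^2))

    if (p$acc_bias > 0) {
      u <- stats::rnorm(3)
      f_s <- sweep(f_s, 2, -(u / sqrt(sum(u^2)) * p$acc_bias))
    }
    if (p$noise_sigma_acc > 0) {
      f_s <- f_s + matrix(stats::rnorm(3 * N, sd = p$noise_sigma_acc), N, 3)
    }
    if (p$noise_sigma_gyr > 0) {
      w_s <- w_s + matrix(stats::rnorm(3 * N, sd = p$noise_sigma_gyr), N, 3)
    }
    sensors[[si]] <- sensor_recording(ids[si], f_s, w_s)
  }

  trial <- imu_trial(sensors, fs = fs,
                     static_interval = c(1L, onset - 1L),
                     config = p$config, labels = labels, trial_id = trial_id)
  # ground-truth stride boundaries: peaks of the constructed (noise-free)
  # summed-magnitude waveform, every second peak
  boundaries <- detect_walking_cycles(summary_nf, fs)$boundaries
  attr(trial, "truth") <- list(heading_deg = p$heading_deg,
                               boundaries = boundaries, onset = onset,
                               params = p)
  trial
}

#' Simulate a corpus of walking trials
#'
#' Mirrors a multi-subject recording session: per-trial jitter of walking
#' speed, stride period and signal amplitudes, fresh mounting rotations and
#' noise for every trial. Deterministic given `seed`.
#'
#' @param n_trials number of trials (>= 2)
#' @param seed integer seed
#' @param config configuration name or [sensor_config()]
#' @param jitter logical; jitter speed/stride/amplitudes across trials
#' @param ... overrides passed to [gait_params()] (e.g. `noise_sigma_acc = 0`)
#' @return list of simulated trials
#' @export
make_corpus <- function(n_trials, seed = 1, config = "full_body",
                        jitter = TRUE, ...) {
  if (n_trials < 2) stop("a corpus needs >= 2 trials")
  set.seed(seed)
  jit <- function(lo, hi) stats::runif(1, lo, hi)
  lapply(seq_len(n_trials), function(i) {
    overrides <- list(...)
    base <- list(config = config,
                 seed = (seed * 1009 + i * 7919) %% 2147483647)
    if (jitter) {
      base$walking_speed <- 1.39 * jit(0.9, 1.1)
      base$stride_period <- 1.1 * jit(0.93, 1.07)
      base$amp_scale <- jit(0.9, 1.1)
      base$arm_swing_amplitude <- jit(0.9, 1.1)
      base$pelvis_roll_amplitude <- jit(0.85, 1.15)
      base$heading_deg <- jit(-180, 180)
    }
    base[names(overrides)] <- overrides
    simulate_trial(do.call(gait_params, base), trial_id = sprintf("T%03d", i))
  })
}
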