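# Feature extraction. Per sensor and kinematic signal (acceleration a,
# angular velocity w, angular acceleration alpha): RMS and variance of the
# magnitude and of the x/y/z components, sum and maximum of the
# between-sensor correlation coefficients (per component, diagonal excluded),
# and the three inter-axis correlations -- 19 features per signal, 57 per
# sensor. Tables can be fractionally ranked, z-scored, or left raw (raw mode
# drops the between-sensor correlation families, which require a known
# configuration).

SIGNAL_KEYS <- c(a = "acc", w = "gyr", alpha = "angacc")
COMPONENTS <- c("mag", "x", "y", "z")
CROSS_SENSOR_FAMILIES <- c("SumCC", "MaxCC")

#' Feature name registry
#'
#' Stable feature names in canonical order, e.g. `RMS_mag_a`, `Var_z_w`,
#' `SumCC_x_alpha`, `MaxCC_mag_a`, `IAC_xy_alpha`. Signals are suffixed `a`
#' (acceleration), `w` (angular velocity), `alpha` (angular acceleration).
#'
#' @param mode `"rank"`, `"normalize"` or `"raw"`; raw mode omits the
#'   between-sensor correlation families (`SumCC`, `MaxCC`)
#' @return character vector of feature names (57, or 33 in raw mode)
#' @export
feature_registry <- function(mode = c("rank", "normalize", "raw")) {
  mode <- match.arg(mode)
  out <- character(0)
  for (sig in names(SIGNAL_KEYS)) {
    fams <- c("RMS", "Var",
              if (mode != "raw") CROSS_SENSOR_FAMILIES)
    for (fam in fams) out <- c(out, paste(fam, COMPONENTS, sig, sep = "_"))
    out <- c(out, paste("IAC", c("xy", "xz", "yz"), sig, sep = "_"))
  }
  out
}

#' Number of features per sensor for a transform mode
#' @inheritParams feature_registry
#' @return integer: 57 in rank/normalize modes, 33 in raw mode
#' @export
count_features <- function(mode = c("rank", "normalize", "raw")) {
  length(feature_registry(mode))
}

# Pearson correlation that maps zero-variance input to 0 instead of NA
safe_cor <- function(x, y) {
  if (stats::sd(x) < .Machine$double.eps * 100 ||
      stats::sd(y) < .Machine$double.eps * 100) {
    warning("zero-variance series in correlation; feature set to 0")
    return(0)
  }
  stats::cor(x, y)
}

# column-wise correlation matrix with zero-variance columns mapped to 0
safe_cor_matrix <- function(M) {
  sds <- apply(M, 2, stats::sd)
  C <- suppressWarnings(stats::cor(M))
  bad <- sds < .Machine$double.eps * 100
  if (any(bad)) {
    warning("zero-variance series in correlation matrix; entries set to 0")
    C[bad, ] <- 0
    C[, bad] <- 0
    diag(C) <- 1
  }
  C
}

# the four component series (magnitude, x, y, z) of an N x 3 signal
signal_components <- function(M) {
  cbind(mag = sqrt(rowSums(M^2)), x = M[, 1], y = M[, 2], z = M[, 3])
}

#' Per-sensor features of one sensor's gait-frame signals
#'
#' RMS and variance of magnitude/x/y/z plus the three inter-axis correlation
#' coefficients, for each of acceleration, angular velocity and angular
#' acceleration (11 features per signal; the between-sensor families are
#' added by [cross_sensor_features()]).
#'
#' @param sig list with `acc`, `gyr`, `angacc` (N x 3, gait frame), already
#'   restricted to the analysis window
#' @return named numeric vector of 33 features
#' @export
per_sensor_features <- function(sig) {
  out <- c()
  for (s in names(SIGNAL_KEYS)) {
    M <- sig[[SIGNAL_KEYS[[s]]]]
    if (nrow(M) < 2) stop("need >= 2 samples in the analysis window")
    comp <- signal_components(M)
    rms <- sqrt(colMeans(comp^2))
    vr <- apply(comp, 2, stats::var)
    iac <- c(xy = safe_cor(M[, 1], M[, 2]),
             xz = safe_cor(M[, 1], M[, 3]),
             yz = safe_cor(M[, 2], M[, 3]))
    names(rms) <- paste("RMS", COMPONENTS, s, sep = "_")
    names(vr) <- paste("Var", COMPONENTS, s, sep = "_")
    names(iac) <- paste("IAC", c("xy", "xz", "yz"), s, sep = "_")
    out <- c(out, rms, vr, iac)
  }
  out
}

#' Between-sensor correlation features
#'
#' For every kinematic signal and component, the Pearson correlation matrix
#' across sensors is computed; each sensor's features are its row sum and row
#' maximum with the autocorrelation diagonal excluded.
#'
#' @param sigs named list (per sensor) of gait-frame signal lists restricted
#'   to the analysis window
#' @return matrix, one row per sensor, 24 columns (`SumCC_*`, `MaxCC_*`)
#' @export
cross_sensor_features <- function(sigs) {
  if (length(sigs) < 2) {
    stop("between-sensor correlation features require >= 2 sensors")
  }
  n <- length(sigs)
  cols <- list()
  for (s in names(SIGNAL_KEYS)) {
    comp_list <- lapply(sigs, function(g) signal_components(g[[SIGNAL_KEYS[[s]]]]))
    for (ci in seq_along(COMPONENTS)) {
      M <- sapply(comp_list, function(x) x[, ci])
      C <- safe_cor_matrix(M)
      diag(C) <- NA
      cols[[paste("SumCC", COMPONENTS[ci], s, sep = "_")]] <-
        rowSums(C, na.rm = TRUE)
      cols[[paste("MaxCC", COMPONENTS[ci], s, sep = "_")]] <-
        apply(C, 1, max, na.rm = TRUE)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- names(sigs)
  out
}

#' Fractional ranking ("1 2.5 2.5 4")
#'
#' Ascending ranks 1..n with tied values receiving the mean of the ordinal
#' ranks they would occupy; ranks always sum to n(n+1)/2.
#'
#' @param values numeric vector (finite)
#' @return numeric vector of fractional ranks
#' @export
fractional_rank <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values cannot be ranked")
  rank(values, ties.method = "average")
}

#' Extract the full feature table of one preprocessed trial
#'
#' One row per sensor, 57 feature columns (raw values; apply
#' [transform_table()] for the ranked or normalized variants), computed over
#' the trial's analysis window (the first `n_cycles` walking cycles).
#'
#' @param pre a `preprocessed_trial` from [preprocess_trial()]
#' @return data.frame with `trial_id`, `sensor_id`, optional `label`, and one
#'   column per feature; attribute `transform = "none"`
#' @export
extract_features <- function(pre) {
  w <- pre$window[1]:pre$window[2]
  sigs <- lapply(pre$sensors, function(g) {
    list(acc = g$acc[w, , drop = FALSE],
         gyr = g$gyr[w, , drop = FALSE],
         angacc = g$angacc[w, , drop = FALSE])
  })
  per <- t(sapply(sigs, per_sensor_features))
  cross <- cross_sensor_features(sigs)
  feats <- cbind(per, cross)[, feature_registry("rank"), drop = FALSE]
  df <- data.frame(trial_id = pre$trial_id, sensor_id = names(pre$sensors),
                   feats, check.names = FALSE, row.names = NULL)
  if (!is.null(pre$labels)) df$label <- unname(pre$labels[df$sensor_id])
  df <- df[, c("trial_id", "sensor_id",
               if (!is.null(pre$labels)) "label",
               feature_registry("rank"))]
  attr(df, "transform") <- "none"
  df
}

#' Transform a feature table (fractional rank, z-score, or raw)
#'
#' Transforms are applied per trial: each feature column is ranked (or
#' z-scored) across the sensors of one trial, so the result is comparable
#' between trials regardless of walking speed or subject. Raw mode keeps the
#' actual values but drops the between-sensor correlation features, which are
#' only meaningful when the sensor configuration is known.
#'
#' @param table feature table from [extract_features()] (possibly row-bound
#'   over trials)
#' @param mode `"rank"`, `"normalize"` or `"raw"`
#' @return transformed feature table, attribute `transform` set to `mode`
#' @export
transform_table <- function(table, mode = c("rank", "normalize", "raw")) {
  mode <- match.arg(mode)
  fcols <- intersect(feature_registry("rank"), names(table))
  if (mode == "raw") {
    keep <- setdiff(names(table),
                    grep("^(SumCC|MaxCC)_", names(table), value = TRUE))
    out <- table[, keep, drop = FALSE]
  } else {
    out <- table
    for (tid in unique(table$trial_id)) {
      i <- which(table$trial_id == tid)
      for (fc in fcols) {
        v <- table[[fc]][i]
        out[[fc]][i] <- if (mode == "rank") {
          fractional_rank(v)
        } else {
          s <- stats::sd(v)
          if (s < .Machine$double.eps * 100) {
            warning("zero spread in feature ", fc, "; normalized to 0")
            rep(0, length(v))
          } else {
            (v - mean(v)) / s
          }
        }
      }
    }
  }
  attr(out, "transform") <- mode
  out
}

#' Trunk orientation by trapezoidal integration and detrending
#'
#' For trunk sensors (pelvis, sternum) the orientation excursions during
#' walking are small, so the gait-frame angular velocity is integrated
#' per axis (trapezoidal rule) and linearly detrended instead of solving the
#' full orientation differential equation.
#'
#' @param gyr N x 3 gait-frame angular velocity (analysis window), rad/s
#' @param fs sampling frequency, Hz
#' @return N x 3 matrix of detrended orientation angles, radians
#' @export
trunk_orientation <- function(gyr, fs) {
  th <- apply(as.matrix(gyr), 2, pracma::cumtrapz) / fs
  pracma::detrend(th, tt = "linear")
}

# the 15 limb series used for left/right training features: accelerations,
# velocities, angular velocities, angular accelerations and orientations
# (x, y, z each); velocities and orientations by trapezoidal integration of
# the windowed signal plus linear detrend, mirroring the trunk recipe
limb_series <- function(sig, fs) {
  integ <- function(M) pracma::detrend(apply(M, 2, pracma::cumtrapz) / fs,
                                       tt = "linear")
  list(a = sig$acc, v = integ(sig$acc), w = sig$gyr,
       alpha = sig$angacc, theta = integ(sig$gyr))
}

#' Left/right correlation features of a limb sensor with the trunk
#'
#' The 45 Pearson correlations between the limb's 15 series (accelerations,
#' velocities, angular velocities, angular accelerations and orientations;
#' x, y, z each) and the 3 trunk orientation components.
#'
#' @param sig limb gait-frame signals (analysis window): list with `acc`,
#'   `gyr`, `angacc`
#' @param trunk N x 3 trunk orientation from [trunk_orientation()]
#' @param fs sampling frequency, Hz
#' @return named numeric vector of 45 correlations, names
#'   `cc_<series><axis>_theta<axis>` (e.g. `cc_az_thetax`)
#' @export
step2_features <- function(sig, trunk, fs) {
  ser <- limb_series(sig, fs)
  axes <- c("x", "y", "z")
  out <- numeric(0)
  for (ty in names(ser)) {
    for (i in 1:3) {
      for (j in 1:3) {
        nm <- paste0("cc_", ty, axes[i], "_theta", axes[j])
        out[nm] <- safe_cor(ser[[ty]][, i], trunk[, j])
      }
    }
  }
  out
}

# Table of adjacency rules for left/right chaining: each still-unresolved
# class is correlated with its resolved neighbour on one acceleration
# component, and the larger correlation indicates the same lateral side.
STEP3_RULES <- list(
  shoulder = list(neighbor = "upper_arm", component = "z"),
  forearm = list(neighbor = "upper_arm", component = "x"),
  hand = list(neighbor = "forearm", component = "y"),
  lower_leg = list(neighbor = "upper_leg", component = "x"),
  foot = list(neighbor = "lower_leg", component = "x")
)

#' Candidate-by-neighbour correlations for left/right chaining
#'
#' For a pair of same-class candidate sensors and the already-resolved
#' left/right neighbour sensors, returns the 2 x 2 matrix of Pearson
#' correlations on the acceleration component prescribed for that segment
#' class (z for shoulders vs upper arms, x for forearms/upper arms,
#' y for hands/forearms, x for lower legs/upper legs and feet/lower legs).
#'
#' @param candidates named list (2) of gait-frame signals of the unresolved
#'   pair
#' @param neighbors named list with elements `left` and `right`: gait-frame
#'   signals of the resolved adjacent segments
#' @param class segment class of the candidates (e.g. `"foot"`)
#' @return 2 x 2 matrix, rows = candidates, columns = `left`, `right`
#' @export
step3_features <- function(candidates, neighbors, class) {
  rule <- STEP3_RULES[[class]]
  if (is.null(rule)) stop("no left/right chaining rule for class ", class)
  if (!all(c("left", "right") %in% names(neighbors))) {
    stop("neighbors must be resolved (named left and right)")
  }
  ci <- match(rule$component, c("x", "y", "z"))
  out <- matrix(0, 2, 2, dimnames = list(names(candidates), c("left", "right")))
  for (i in 1:2) {
    for (sd_ in c("left", "right")) {
      out[i, sd_] <- safe_cor(candidates[[i]]$acc[, ci],
                              neighbors[[sd_]]$acc[, ci])
    }
  }
  out
}
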