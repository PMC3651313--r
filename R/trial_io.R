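# Trial container and open-format I/O: one CSV per sensor (time, ax, ay, az,
# gx, gy, gz) plus a JSON manifest declaring sampling rate, static interval,
# units, configuration and (optionally) ground-truth labels. Feature tables
# are exchanged as ARFF (Weka dialect) or CSV; trained models as JSON.

#' Single sensor recording
#'
#' @param sensor_id character scalar
#' @param acc N x 3 matrix, accelerometer specific force, m/s^2, sensor frame
#' @param gyr N x 3 matrix, angular velocity, rad/s, sensor frame
#' @return object of class `sensor_recording`
#' @export
sensor_recording <- function(sensor_id, acc, gyr) {
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  if (ncol(acc) != 3 || ncol(gyr) != 3) stop("acc and gyr must have 3 columns")
  if (nrow(acc) != nrow(gyr)) {
    stop("sensor ", sensor_id, ": acc and gyr lengths differ")
  }
  if (nrow(acc) < 2) stop("sensor ", sensor_id, ": needs >= 2 samples")
  for (nm in c("acc", "gyr")) {
    m <- get(nm)
    if (any(!is.finite(m))) {
      idx <- which(!is.finite(m), arr.ind = TRUE)[1, 1]
      stop("sensor ", sensor_id, ": non-finite ", nm, " at sample ", idx)
    }
  }
  structure(list(sensor_id = sensor_id, acc = unname(acc), gyr = unname(gyr)),
            class = "sensor_recording")
}

#' Walking trial: synchronized sensor recordings plus metadata
#'
#' @param sensors list of [sensor_recording()] objects
#' @param fs sampling frequency, Hz
#' @param static_interval integer `c(start, end)`, 1-based inclusive sample
#'   indices of the static standing interval; `NULL` to auto-detect via
#'   [detect_static_interval()]
#' @param config a [sensor_config()]
#' @param labels optional named character vector, sensor_id -> segment label
#' @param trial_id character scalar identifier
#' @return object of class `imu_trial`
#' @export
imu_trial <- function(sensors, fs, static_interval = NULL,
                      config = sensor_config("full_body"), labels = NULL,
                      trial_id = "trial") {
  if (fs <= 0) stop("fs must be positive")
  ids <- vapply(sensors, `[[`, "", "sensor_id")
  if (anyDuplicated(ids)) stop("duplicate sensor ids")
  names(sensors) <- ids
  n <- vapply(sensors, function(s) nrow(s$acc), 0L)
  if (length(unique(n)) != 1) {
    stop("ragged recordings: lengths ", paste(unique(n), collapse = ", "))
  }
  if (length(sensors) != config$n_sensors) {
    stop("trial has ", length(sensors), " sensors but configuration '",
         config$name, "' requires ", config$n_sensors)
  }
  validate_labels(labels, config, ids)
  trial <- structure(
    list(sensors = sensors, fs = fs, static_interval = static_interval,
         config = config, labels = labels, trial_id = trial_id,
         n_samples = n[[1]]),
    class = "imu_trial"
  )
  if (is.null(static_interval)) {
    trial$static_interval <- detect_static_interval(trial)
  } else {
    si <- static_interval
    if (length(si) != 2 || si[1] < 1 || si[2] <= si[1] || si[2] > n[[1]]) {
      stop("invalid static interval")
    }
  }
  trial
}

#' @export
print.imu_trial <- function(x, ...) {
  cat("<imu_trial>", x$trial_id, "-", length(x$sensors), "sensors,",
      x$n_samples, "samples @", x$fs, "Hz\n")
  cat("  static: samples", x$static_interval[1], "-", x$static_interval[2],
      if (!is.null(x$labels)) " (labelled)" else "", "\n")
  invisible(x)
}

.unit_factor <- function(unit, kind) {
  acc_units <- c("m/s^2" = 1, "m/s²" = 1, "g" = GRAVITY)
  gyr_units <- c("rad/s" = 1, "deg/s" = pi / 180)
  tab <- if (kind == "acc") acc_units else gyr_units
  if (!unit %in% names(tab)) {
    stop("unknown ", kind, " unit '", unit, "'")
  }
  tab[[unit]]
}

#' Write a trial to a directory (per-sensor CSVs + JSON manifest)
#'
#' @param trial an [imu_trial()]
#' @param dir output directory (created if missing)
#' @param meta optional named list stored verbatim in the manifest (e.g.
#'   simulation seed and parameters)
#' @return path to the manifest, invisibly
#' @export
write_trial <- function(trial, dir, meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tvec <- (seq_len(trial$n_samples) - 1) / trial$fs
  files <- list()
  for (s in trial$sensors) {
    df <- data.frame(time = tvec,
                     ax = s$acc[, 1], ay = s$acc[, 2], az = s$acc[, 3],
                     gx = s$gyr[, 1], gy = s$gyr[, 2], gz = s$gyr[, 3])
    fn <- paste0(s$sensor_id, ".csv")
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    files[[s$sensor_id]] <- fn
  }
  manifest <- list(
    schema_version = 1L,
    trial_id = trial$trial_id,
    fs = trial$fs,
    static_interval = as.integer(trial$static_interval),
    units = list(acc = "m/s^2", gyr = "rad/s"),
    configuration = list(name = trial$config$name,
                         segments = trial$config$segments),
    sensors = files,
    labels = if (!is.null(trial$labels)) as.list(trial$labels) else NULL,
    meta = meta
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a trial from a manifest written by [write_trial()]
#'
#' Units declared in the manifest (`m/s^2` or `g`; `rad/s` or `deg/s`) are
#' converted to the internal m/s^2 and rad/s at this boundary.
#'
#' @param manifest_path path to `manifest.json`
#' @return an [imu_trial()]
#' @export
read_trial <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$schema_version) || man$schema_version != 1) {
    stop("unsupported trial manifest schema version")
  }
  dir <- dirname(manifest_path)
  fa <- .unit_factor(man$units$acc, "acc")
  fg <- .unit_factor(man$units$gyr, "gyr")
  sensors <- lapply(names(man$sensors), function(id) {
    fn <- file.path(dir, man$sensors[[id]])
    if (!file.exists(fn)) stop("missing sensor file for ", id, ": ", fn)
    df <- utils::read.csv(fn)
    need <- c("ax", "ay", "az", "gx", "gy", "gz")
    if (!all(need %in% names(df))) {
      stop("sensor ", id, ": CSV must have columns ", paste(need, collapse = ", "))
    }
    sensor_recording(id,
                     acc = as.matrix(df[, c("ax", "ay", "az")]) * fa,
                     gyr = as.matrix(df[, c("gx", "gy", "gz")]) * fg)
  })
  config <- if (identical(man$configuration$name, "custom")) {
    sensor_config("custom", segments = man$configuration$segments)
  } else {
    sensor_config(man$configuration$name)
  }
  labels <- if (!is.null(man$labels)) unlist(man$labels) else NULL
  imu_trial(sensors, fs = man$fs,
            static_interval = man$static_interval,
            config = config, labels = labels, trial_id = man$trial_id)
}

#' Write a feature table to ARFF (Weka dialect) or CSV
#'
#' The ARFF file declares one numeric attribute per feature plus a nominal
#' `class` attribute; unlabelled rows get the missing marker `?`. The CSV
#' format keeps the `trial_id` and `sensor_id` bookkeeping columns.
#'
#' @param table a feature table from [extract_features()]
#' @param path output file
#' @param format `"arff"` or `"csv"`
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path, format = c("arff", "csv")) {
  format <- match.arg(format)
  if (!nrow(table)) stop("empty feature table")
  if (format == "csv") {
    df <- table
    attr(df, "transform") <- NULL
    utils::write.csv(cbind(transform = feature_transform(table), df), path,
                     row.names = FALSE)
  } else {
    feats <- table[, feature_columns(table), drop = FALSE]
    cls <- factor(
      if ("label" %in% names(table)) segment_class(table$label) else
        rep(NA_character_, nrow(table)),
      levels = SEGMENT_CLASSES
    )
    foreign::write.arff(cbind(feats, class = cls), path)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path input file
#' @param format `"arff"` or `"csv"`
#' @return data.frame of features (plus `class` column for ARFF)
#' @export
read_feature_table <- function(path, format = c("arff", "csv")) {
  format <- match.arg(format)
  if (format == "arff") foreign::read.arff(path) else utils::read.csv(path)
}

#' Names of the columns of a feature table that hold feature values
#' @param table a feature table from [extract_features()]
#' @return character vector of feature column names
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("trial_id", "sensor_id", "label"))
}

feature_transform <- function(table) {
  tr <- attr(table, "transform")
  if (is.null(tr)) "raw" else tr
}

#' Serialize an identification model to JSON
#' @param model an `ident_model` from [train_pipeline()]
#' @param path output file
#' @return `path`, invisibly
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "ident_model"))
  obj <- list(
    schema_version = 1L,
    config = list(name = model$config$name, segments = model$config$segments),
    transform = model$transform,
    feature_names = model$feature_names,
    step1_tree = tree_to_list(model$step1_tree),
    step2 = list(
      mode = model$step2$mode,
      tree = if (!is.null(model$step2$tree)) tree_to_list(model$step2$tree)
    ),
    step3_rules = model$step3_rules,
    n_cycles = model$n_cycles
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load an identification model written by [serialize_model()]
#' @param path JSON model file
#' @return an `ident_model`
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1) {
    stop("unsupported model schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version)
  }
  config <- if (identical(obj$config$name, "custom")) {
    sensor_config("custom", segments = unlist(obj$config$segments))
  } else {
    sensor_config(obj$config$name)
  }
  structure(
    list(
      config = config,
      transform = obj$transform,
      feature_names = unlist(obj$feature_names),
      step1_tree = tree_from_list(obj$step1_tree),
      step2 = list(mode = obj$step2$mode,
                   tree = if (!is.null(obj$step2$tree))
                     tree_from_list(obj$step2$tree)),
      step3_rules = lapply(obj$step3_rules, function(r)
        list(neighbor = r$neighbor, component = r$component)),
      n_cycles = obj$n_cycles
    ),
    class = "ident_model"
  )
}
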