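# Three-step identification: (1) segment-class classification of ranked
# features with the decision tree, with a multiplicity check against the
# configuration; (2) left/right disambiguation of upper arms (vs sternum
# roll) and upper legs (vs pelvis roll) -- the candidate whose vertical
# acceleration correlates most positively with the trunk roll is the right
# one; (3) left/right chaining of the remaining paired segments through
# already-resolved neighbours (shoulders and forearms from upper arms, hands
# from forearms, lower legs from upper legs, feet from lower legs).

CC_TIE_TOL <- 1e-6

#' Train an identification model on labelled trials
#'
#' Step 1 is a decision tree built on the pooled per-trial-transformed
#' feature tables with segment classes (sides stripped) as labels. Step 2
#' defaults to the fixed trunk-roll correlation rule; `step2 = "tree"`
#' instead trains a small decision tree on the 45 ranked limb-trunk
#' correlations. Step 3 uses the fixed adjacency component rules.
#'
#' @param trials list of labelled [imu_trial()] objects (or preprocessed
#'   trials)
#' @param config a [sensor_config()] (or name); must match the trials
#' @param transform feature transform: `"rank"` (default), `"normalize"`, or
#'   `"raw"` (configuration-unknown mode: no ranking, no between-sensor
#'   correlations, reduced reliability)
#' @param step2 `"rule"` (default) or `"tree"`
#' @param n_cycles walking cycles used per trial (1-3, default 3)
#' @param ... passed to [build_tree()]
#' @return object of class `ident_model`
#' @export
train_pipeline <- function(trials, config = "full_body", transform = "rank",
                           step2 = c("rule", "tree"), n_cycles = 3, ...) {
  step2 <- match.arg(step2)
  if (is.character(config)) config <- sensor_config(config)
  if (length(trials) < 2) stop("training needs >= 2 labelled trials")
  pres <- lapply(trials, function(tr) {
    if (inherits(tr, "preprocessed_trial")) tr else
      preprocess_trial(tr, n_cycles = n_cycles)
  })
  for (pre in pres) {
    if (is.null(pre$labels)) stop("all training trials must be labelled")
    if (!identical(pre$config$segments, config$segments)) {
      stop("trial ", pre$trial_id, " configuration does not match")
    }
  }
  tab <- do.call(rbind, lapply(pres, extract_features))
  tab <- transform_table(tab, transform)
  y <- factor(segment_class(tab$label), levels = SEGMENT_CLASSES)
  y <- droplevels(y)
  want <- unique(segment_class(config$segments))
  if (!setequal(levels(y), want)) {
    stop("training labels missing class(es): ",
         paste(setdiff(want, levels(y)), collapse = ", "))
  }
  fcols <- feature_columns(tab)
  tree <- build_tree(tab[, fcols, drop = FALSE], y, ...)

  step2_tree <- NULL
  if (step2 == "tree") {
    s2 <- do.call(rbind, lapply(pres, step2_training_rows))
    step2_tree <- build_tree(s2[, setdiff(names(s2), "side"), drop = FALSE],
                             factor(s2$side), ...)
  }

  structure(
    list(config = config, transform = transform, feature_names = fcols,
         step1_tree = tree, step2 = list(mode = step2, tree = step2_tree),
         step3_rules = STEP3_RULES, n_cycles = n_cycles),
    class = "ident_model"
  )
}

#' @export
print.ident_model <- function(x, ...) {
  cat("<ident_model>", x$config$name, "/", x$transform, "features /",
      "step2:", x$step2$mode, "\n")
  invisible(x)
}

# windowed gait-frame signals of one sensor
.windowed <- function(pre, id) {
  w <- pre$window[1]:pre$window[2]
  g <- pre$sensors[[id]]
  list(acc = g$acc[w, , drop = FALSE], gyr = g$gyr[w, , drop = FALSE],
       angacc = g$angacc[w, , drop = FALSE])
}

# ranked step-2 correlation features for training the optional step-2 tree:
# one row per upper arm / upper leg sensor, ranked within the pair
step2_training_rows <- function(pre) {
  seg_of <- pre$labels
  rows <- list()
  for (cls in intersect(c("upper_arm", "upper_leg"),
                        segment_class(pre$config$segments))) {
    trunk_cls <- if (cls == "upper_arm") "sternum" else "pelvis"
    trunk_id <- names(seg_of)[seg_of == trunk_cls]
    trunk <- trunk_orientation(.windowed(pre, trunk_id)$gyr, pre$fs)
    ids <- names(seg_of)[segment_class(seg_of) == cls]
    cc <- t(sapply(ids, function(id)
      step2_features(.windowed(pre, id), trunk, pre$fs)))
    ranked <- apply(cc, 2, fractional_rank)
    df <- as.data.frame(ranked)
    df$side <- segment_side(seg_of[ids])
    rows[[cls]] <- df
  }
  do.call(rbind, rows)
}

# step 1: classes + multiplicity repair. Returns list(class = named vector,
# flags = character)
classify_step1 <- function(model, tab) {
  fcols <- model$feature_names
  miss <- setdiff(fcols, names(tab))
  if (length(miss)) stop("feature table lacks: ", paste(miss, collapse = ", "))
  pred <- predict(model$step1_tree, tab[, fcols, drop = FALSE])
  names(pred) <- tab$sensor_id
  flags <- character(0)
  expected <- config_class_counts(model$config)
  have <- table(factor(pred, levels = names(expected)))
  if (!all(have == expected)) {
    # repair: greedily keep the most confident predictions within each
    # class's capacity, reassign surplus sensors by leaf class probability
    P <- predict(model$step1_tree, tab[, fcols, drop = FALSE], type = "prob")
    P <- P[, intersect(colnames(P), names(expected)), drop = FALSE]
    rownames(P) <- tab$sensor_id
    cap <- stats::setNames(as.integer(expected), names(expected))
    assigned <- stats::setNames(rep(NA_character_, nrow(P)), rownames(P))
    Q <- P
    repeat {
      if (!any(is.na(assigned))) break
      open <- names(cap)[cap > 0]
      sub <- Q[is.na(assigned), open, drop = FALSE]
      i <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      sid <- rownames(sub)[i[1]]
      cls <- open[i[2]]
      assigned[sid] <- cls
      cap[cls] <- cap[cls] - 1L
    }
    flags <- c(flags, paste0(
      "step1 multiplicity violation repaired (predicted ",
      paste(names(have)[have != expected], collapse = ","), ")"))
    pred <- assigned[names(pred)]
  }
  list(class = pred, flags = flags)
}

# step 2: resolve one sided pair against the trunk roll; returns named sides
classify_step2_pair <- function(pre, cand_ids, trunk_id, step2_model = NULL) {
  trunk <- trunk_orientation(.windowed(pre, trunk_id)$gyr, pre$fs)
  flags <- character(0)
  if (!is.null(step2_model)) {
    cc <- t(sapply(cand_ids, function(id)
      step2_features(.windowed(pre, id), trunk, pre$fs)))
    ranked <- as.data.frame(apply(cc, 2, fractional_rank))
    pred <- predict(step2_model, ranked)
    if (length(unique(pred)) != 2) {
      P <- predict(step2_model, ranked, type = "prob")
      first <- which.max(P[, pred[1]])
      pred <- if (first == 1) c(pred[1], setdiff(c("left", "right"), pred[1]))
      else c(setdiff(c("left", "right"), pred[1]), pred[1])
      flags <- "step2 tree predicted one side twice; resolved by margin"
    }
    sides <- stats::setNames(pred, cand_ids)
    return(list(sides = sides, flags = flags))
  }
  cc <- vapply(cand_ids, function(id)
    safe_cor(.windowed(pre, id)$acc[, 3], trunk[, 1]), numeric(1))
  if (abs(cc[1] - cc[2]) < CC_TIE_TOL) {
    flags <- paste0("step2 ambiguous (|cc difference| < ", CC_TIE_TOL,
                    ") for ", paste(cand_ids, collapse = ","))
  }
  right <- cand_ids[which.max(cc)]
  sides <- stats::setNames(ifelse(cand_ids == right, "right", "left"),
                           cand_ids)
  list(sides = sides, flags = flags, cc = cc)
}

# step 3: chain left/right through resolved neighbours
classify_step3_pair <- function(pre, cand_ids, neighbor_ids, cls) {
  cands <- lapply(cand_ids, function(id) .windowed(pre, id))
  names(cands) <- cand_ids
  neigh <- list(left = .windowed(pre, neighbor_ids[["left"]]),
                right = .windowed(pre, neighbor_ids[["right"]]))
  M <- step3_features(cands, neigh, cls)
  flags <- character(0)
  pick <- apply(M, 1, function(r) colnames(M)[which.max(r)])
  margin <- abs(M[, "left"] - M[, "right"])
  if (any(margin < CC_TIE_TOL)) {
    flags <- c(flags, paste0("step3 ambiguous correlation for class ", cls))
  }
  if (pick[1] == pick[2]) {
    keep <- which.max(margin)
    pick[-keep] <- setdiff(c("left", "right"), pick[keep])
    flags <- c(flags, paste0("step3 both ", cls,
                             " candidates preferred the same side; ",
                             "assigned by margin"))
  }
  list(sides = stats::setNames(pick, cand_ids), flags = flags)
}

#' Identify the segment of every sensor in a trial
#'
#' Runs the three identification steps with a trained model. When the trial
#' carries ground-truth labels the per-step accuracies are reported.
#'
#' @param model an `ident_model` from [train_pipeline()] or [load_model()]
#' @param trial an [imu_trial()] or `preprocessed_trial`
#' @return object of class `ident_result`: `assignment` (named sensor_id ->
#'   segment label, a bijection onto the configuration), `step1_class`,
#'   `flags`, and (when labels are present) `accuracy` with elements `step1`,
#'   `step2`, `step3`, `overall`
#' @export
identify_trial <- function(model, trial) {
  pre <- if (inherits(trial, "preprocessed_trial")) trial else
    preprocess_trial(trial, n_cycles = model$n_cycles)
  if (pre$config$n_sensors != model$config$n_sensors) {
    stop("trial has ", pre$config$n_sensors, " sensors but the model expects ",
         model$config$n_sensors)
  }
  tab <- transform_table(extract_features(pre), model$transform)
  s1 <- classify_step1(model, tab)
  cls <- s1$class
  flags <- s1$flags

  assignment <- stats::setNames(rep(NA_character_, length(cls)), names(cls))
  for (u in UNSIDED_CLASSES) {
    assignment[names(cls)[cls == u]] <- u
  }

  classes_present <- unique(segment_class(model$config$segments))
  sided_present <- setdiff(classes_present, UNSIDED_CLASSES)
  resolved <- list()   # class -> c(left = id, right = id)

  step2_classes <- intersect(c("upper_arm", "upper_leg"), sided_present)
  for (p2 in step2_classes) {
    trunk_cls <- if (p2 == "upper_arm") "sternum" else "pelvis"
    trunk_id <- names(cls)[cls == trunk_cls]
    ids <- names(cls)[cls == p2]
    r <- classify_step2_pair(pre, ids, trunk_id,
                             if (model$step2$mode == "tree") model$step2$tree)
    flags <- c(flags, r$flags)
    assignment[ids] <- paste(p2, r$sides[ids], sep = "_")
    resolved[[p2]] <- stats::setNames(names(r$sides)[match(c("left", "right"),
                                                           r$sides)],
                                      c("left", "right"))
  }

  step3_order <- intersect(c("shoulder", "forearm", "hand",
                             "lower_leg", "foot"), sided_present)
  for (p3 in step3_order) {
    rule <- model$step3_rules[[p3]]
    ids <- names(cls)[cls == p3]
    nb <- resolved[[rule$neighbor]]
    if (is.null(nb)) stop("step3: neighbour class ", rule$neighbor,
                          " was not resolved before ", p3)
    r <- classify_step3_pair(pre, ids, nb, p3)
    flags <- c(flags, r$flags)
    assignment[ids] <- paste(p3, r$sides[ids], sep = "_")
    resolved[[p3]] <- stats::setNames(names(r$sides)[match(c("left", "right"),
                                                           r$sides)],
                                      c("left", "right"))
  }

  if (anyDuplicated(assignment) || any(is.na(assignment)) ||
      !setequal(assignment, model$config$segments)) {
    flags <- c(flags, "assignment is not a bijection onto the configuration")
  }

  res <- list(assignment = assignment, step1_class = cls, flags = flags,
              trial_id = pre$trial_id)
  if (!is.null(pre$labels)) {
    truth <- pre$labels[names(assignment)]
    s1_acc <- mean(cls == segment_class(truth))
    sided <- segment_side(truth) != "none"
    s2_ids <- names(cls)[cls %in% step2_classes]
    s3_ids <- names(cls)[cls %in% step3_order]
    acc_of <- function(ids) if (length(ids)) {
      mean(assignment[ids] == truth[ids])
    } else NA_real_
    res$accuracy <- list(step1 = s1_acc,
                         step2 = acc_of(s2_ids),
                         step3 = acc_of(s3_ids),
                         overall = mean(assignment == truth))
  }
  structure(res, class = "ident_result")
}

#' @export
print.ident_result <- function(x, ...) {
  cat("<ident_result>", x$trial_id, "\n")
  for (id in names(x$assignment)) {
    cat(" ", id, "->", x$assignment[[id]], "\n")
  }
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy: step1 %.1f%%, overall %.1f%%\n",
                100 * x$accuracy$step1, 100 * x$accuracy$overall))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a model on labelled trials, optionally under perturbations
#'
#' Re-runs preprocessing and identification with an added heading error
#' (Gaussian, per sensor) and/or accelerometer bias (fixed magnitude, random
#' per-sensor direction), and reports per-step accuracies over the corpus --
#' the sensitivity analysis of the identification method.
#'
#' @param model an `ident_model`
#' @param trials list of labelled [imu_trial()] objects
#' @param heading_sigma_deg sd of the heading perturbation, degrees
#' @param acc_bias accelerometer bias magnitude, m/s^2
#' @param seed RNG seed for the perturbations
#' @return data.frame with one row per trial (step accuracies) plus
#'   attribute `summary` (mean accuracies)
#' @export
evaluate_sensitivity <- function(model, trials, heading_sigma_deg = 0,
                                 acc_bias = 0, seed = 1) {
  set.seed(seed)
  rows <- lapply(trials, function(tr) {
    pre <- preprocess_trial(tr, n_cycles = model$n_cycles,
                            heading_noise_sd = heading_sigma_deg * pi / 180,
                            acc_bias = if (acc_bias > 0) acc_bias)
    r <- identify_trial(model, pre)
    data.frame(trial_id = r$trial_id,
               step1 = r$accuracy$step1, step2 = r$accuracy$step2,
               step3 = r$accuracy$step3, overall = r$accuracy$overall)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- colMeans(out[, -1], na.rm = TRUE)
  out
}

#' Velocity error from integrating a constant accelerometer bias
#'
#' Integrates a constant bias acceleration over a time span with the same
#' trapezoidal rule the preprocessing uses, returning the magnitude of the
#' resulting velocity error (e.g. a 0.02 m/s^2 bias over 3 s gives
#' 0.06 m/s).
#'
#' @param bias bias magnitude, m/s^2
#' @param duration integration time, s
#' @param fs sampling frequency, Hz
#' @return velocity error magnitude, m/s
#' @export
bias_velocity_error <- function(bias, duration = 3, fs = 120) {
  n <- round(duration * fs) + 1
  acc <- matrix(rep(c(bias, 0, 0), each = n), n, 3)
  vel <- apply(acc, 2, pracma::cumtrapz) / fs
  sqrt(sum(vel[n, ]^2))
}
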