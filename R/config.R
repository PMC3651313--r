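# Sensor configurations and segment labels.
#
# A segment label is a string such as "pelvis" or "upper_leg_left"; the
# segment class is the label with the side suffix removed. Pelvis, sternum
# and head are unsided.

SEGMENT_CLASSES <- c(
  "pelvis", "sternum", "head", "shoulder", "upper_arm", "forearm", "hand",
  "upper_leg", "lower_leg", "foot"
)
UNSIDED_CLASSES <- c("pelvis", "sternum", "head")

full_body_segments <- function() {
  sided <- setdiff(SEGMENT_CLASSES, UNSIDED_CLASSES)
  c(UNSIDED_CLASSES, as.vector(t(outer(sided, c("right", "left"), paste, sep = "_"))))
}

lower_trunk_segments <- function() {
  sided <- c("upper_leg", "lower_leg", "foot")
  c("pelvis", "sternum", as.vector(t(outer(sided, c("right", "left"), paste, sep = "_"))))
}

#' Sensor configuration
#'
#' Declares the set of body segments carrying a sensor. The two standard
#' configurations are `"full_body"` (17 segments: pelvis, sternum, head and
#' left/right shoulders, upper arms, forearms, hands, upper legs, lower legs
#' and feet) and `"lower_trunk"` (8 segments: pelvis, sternum and left/right
#' upper legs, lower legs and feet).
#'
#' @param name `"full_body"`, `"lower_trunk"`, or `"custom"`
#' @param segments character vector of segment labels; required for
#'   `"custom"`, ignored otherwise
#' @return object of class `sensor_config` with elements `name`, `segments`,
#'   `n_sensors`
#' @export
sensor_config <- function(name = c("full_body", "lower_trunk", "custom"),
                          segments = NULL) {
  name <- match.arg(name)
  segments <- switch(name,
    full_body = full_body_segments(),
    lower_trunk = lower_trunk_segments(),
    custom = segments
  )
  if (is.null(segments) || length(segments) < 2) {
    stop("a configuration needs at least 2 segments")
  }
  if (anyDuplicated(segments)) stop("duplicate segments in configuration")
  bad <- segments[!segment_class(segments) %in% SEGMENT_CLASSES]
  if (length(bad)) stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  structure(
    list(name = name, segments = segments, n_sensors = length(segments)),
    class = "sensor_config"
  )
}

#' @export
print.sensor_config <- function(x, ...) {
  cat("<sensor_config>", x$name, "-", x$n_sensors, "sensors\n")
  cat(" ", paste(x$segments, collapse = ", "), "\n")
  invisible(x)
}

#' Segment class of a segment label (side suffix removed)
#' @param label character vector of segment labels, e.g. `"upper_leg_left"`
#' @return character vector of segment classes, e.g. `"upper_leg"`
#' @export
segment_class <- function(label) sub("_(left|right)$", "", label)

#' Side of a segment label
#' @param label character vector of segment labels
#' @return `"left"`, `"right"` or `"none"` per element
#' @export
segment_side <- function(label) {
  side <- rep("none", length(label))
  side[grepl("_left$", label)] <- "left"
  side[grepl("_right$", label)] <- "right"
  side
}

# expected number of sensors per segment class for a configuration
config_class_counts <- function(config) {
  table(factor(segment_class(config$segments),
               levels = unique(segment_class(config$segments))))
}

# validate that labels (named sensor_id -> segment) are a bijection onto the
# configuration's segment set
validate_labels <- function(labels, config, sensor_ids) {
  if (is.null(labels)) return(invisible(NULL))
  if (!setequal(names(labels), sensor_ids)) {
    stop("labels must name exactly the trial's sensors")
  }
  if (!setequal(unname(labels), config$segments) ||
      anyDuplicated(unname(labels))) {
    stop("labels must be a bijection onto the configuration's segments")
  }
  invisible(NULL)
}
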