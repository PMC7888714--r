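#' Measurement definition
#'
#' Types: `distance` (two landmarks), `angle3` (vertex plus two ray
#' endpoints), `angle_lines` (angle between the directed lines a1->a2 and
#' b1->b2), `bilateral_angle` (mean of a left and a right sub-definition).
#' An optional projection plane (`axial` = x-y, `sagittal` = y-z,
#' `coronal` = x-z) projects the landmarks orthogonally before the angle is
#' taken; superior-view angles use the axial plane, lateral-view angles the
#' sagittal plane.
#'
#' @param name measurement name
#' @param type one of `"distance"`, `"angle3"`, `"angle_lines"`,
#'   `"bilateral_angle"`
#' @param landmarks character vector of landmark names (2 for distance,
#'   vertex-first 3 for angle3, 4 for angle_lines)
#' @param plane `"none"`, `"axial"`, `"sagittal"` or `"coronal"`
#' @param left,right sub-definitions for `bilateral_angle`
#' @return an object of class `measurement_def`
#' @export
measurement_def <- function(name, type, landmarks = character(),
                            plane = "none", left = NULL, right = NULL) {
  type <- match.arg(type, c("distance", "angle3", "angle_lines",
                            "bilateral_angle"))
  plane <- match.arg(plane, c("none", "axial", "sagittal", "coronal"))
  need <- switch(type, distance = 2L, angle3 = 3L, angle_lines = 4L,
                 bilateral_angle = 0L)
  if (type == "bilateral_angle") {
    if (is.null(left) || is.null(right))
      stop("bilateral_angle requires left and right sub-definitions")
  } else if (length(landmarks) != need) {
    stop(type, " requires exactly ", need, " landmarks")
  }
  structure(list(name = name, type = type, landmarks = landmarks,
                 plane = plane, left = left, right = right),
            class = "measurement_def")
}

project_point <- function(p, plane) {
  switch(plane,
         none = p,
         axial = c(p[1L], p[2L], 0),
         sagittal = c(0, p[2L], p[3L]),
         coronal = c(p[1L], 0, p[3L]))
}

vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate angle: zero-length ray (possibly after projection)")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Euclidean inter-landmark distance
#'
#' @param set a [landmark_set()]
#' @param a,b landmark names
#' @return distance in mm
#' @export
interlandmark_distance <- function(set, a, b) {
  sqrt(sum((landmark_xyz(set, a) - landmark_xyz(set, b))^2))
}

#' Evaluate an angle measurement
#'
#' `angle3` is the angle at the vertex (first landmark) between the rays to
#' the other two; `angle_lines` is the angle between the directed lines
#' through the two landmark pairs. Both lie in \[0, 180\] degrees and are
#' invariant under rigid motion (and, unprojected, under uniform scaling).
#'
#' @param set a [landmark_set()]
#' @param def a [measurement_def()] of type `angle3` or `angle_lines`
#' @return angle in degrees
#' @export
angle_measure <- function(set, def) {
  stopifnot(inherits(def, "measurement_def"))
  pr <- function(nm) project_point(landmark_xyz(set, nm), def$plane)
  if (def$type == "angle3") {
    v <- pr(def$landmarks[1L])
    vec_angle_deg(pr(def$landmarks[2L]) - v, pr(def$landmarks[3L]) - v)
  } else if (def$type == "angle_lines") {
    vec_angle_deg(pr(def$landmarks[2L]) - pr(def$landmarks[1L]),
                  pr(def$landmarks[4L]) - pr(def$landmarks[3L]))
  } else {
    stop("angle_measure expects an angle3 or angle_lines definition")
  }
}

#' Average of a left and a right angle
#'
#' The arithmetic mean of the two side measurements; an error is raised if
#' either side is missing rather than silently returning a one-sided value.
#'
#' @param set a [landmark_set()]
#' @param left_def,right_def [measurement_def()]s for the two sides
#' @return mean angle in degrees
#' @export
bilateral_average <- function(set, left_def, right_def) {
  (angle_measure(set, left_def) + angle_measure(set, right_def)) / 2
}

evaluate_one <- function(set, def) {
  switch(def$type,
         distance = interlandmark_distance(set, def$landmarks[1L],
                                           def$landmarks[2L]),
         angle3 = angle_measure(set, def),
         angle_lines = angle_measure(set, def),
         bilateral_angle = bilateral_average(set, def$left, def$right))
}

#' Evaluate a batch of measurements over replicate landmark sets
#'
#' @param sets list of [landmark_set()]s (each carrying `animal` and
#'   `replicate` attributes)
#' @param defs list of [measurement_def()]s
#' @return long-format data frame with one row per (animal, replicate,
#'   measurement); per-measurement errors are collected into an `errors`
#'   attribute instead of aborting the batch
#' @export
evaluate_measurement_set <- function(sets, defs) {
  rows <- list(); errs <- character(); r <- 0L
  for (s in sets) {
    for (d in defs) {
      r <- r + 1L
      val <- tryCatch(evaluate_one(s, d), error = function(e) {
        errs <<- c(errs, paste0(attr(s, "animal"), "/", d$name, ": ",
                                conditionMessage(e)))
        NA_real_
      })
      rows[[r]] <- data.frame(animal = attr(s, "animal") %||% NA_character_,
                              replicate = attr(s, "replicate") %||% NA_integer_,
                              name = d$name, value = val,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errs
  out
}

parse_measurement_def <- function(x) {
  measurement_def(
    name = x$name, type = x$type,
    landmarks = unlist(x$landmarks, use.names = FALSE) %||% character(),
    plane = x$plane %||% "none",
    left = if (!is.null(x$left)) parse_measurement_def(x$left),
    right = if (!is.null(x$right)) parse_measurement_def(x$right))
}

#' Read measurement definitions from YAML
#'
#' The package ships an editable template
#' (`system.file("extdata", "measurements.yaml", package = "wbpleth")`)
#' naming the standard craniofacial endpoints (cranial-base lengths and
#' flexion angles, snout and frontal-bossing angles, bilateral nasal
#' depression angles, nasal width/length). The geometry engine is exact;
#' anatomical landmark placement is user data.
#'
#' @param path YAML file path
#' @return list of [measurement_def()]s
#' @export
read_measurement_defs <- function(path) {
  lapply(yaml::read_yaml(path)$measurements, parse_measurement_def)
}
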