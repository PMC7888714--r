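#' @title Domain records for plethysmography analysis
#' @name trace-core
#' @description
#' Constructors and validators for the core value objects used throughout the
#' package: chamber environment, animal metadata, calibration, protocol epochs,
#' pressure traces, per-breath tables, gas traces and landmark sets. Units are
#' fixed at these boundaries: time in seconds from recording start, pressure in
#' arbitrary transducer units (cancelled by the P_T/P_K ratio), volume in ml,
#' flow in ml/min, temperature stored in degrees Celsius and converted to
#' Kelvin only inside the physiological equations.
NULL

EPOCH_LABELS <- c("normoxia", "hypoxia", "recovery", "hyperoxia")
GROUP_LABELS <- c("ctrl", "ncko_r", "ncko_a", "custom")

#' Chamber environment record
#'
#' @param ta_c chamber air temperature, degrees C
#' @param pb_mmhg barometric pressure, mmHg
#' @param rh chamber relative humidity, fraction in \[0, 1\]
#' @param flow_ml_min chamber gas flow, ml/min
#' @param chamber_ml chamber volume, ml
#' @return an object of class `environment_record`
#' @export
environment_record <- function(ta_c = 25, pb_mmhg = 760, rh = 0.4,
                               flow_ml_min = 300, chamber_ml = 200) {
  stopifnot(is.numeric(ta_c), length(ta_c) == 1L)
  if (ta_c <= -273.15) stop("chamber temperature must be above absolute zero")
  if (rh < 0 || rh > 1) stop("relative humidity must lie in [0, 1]")
  if (pb_mmhg <= 0) stop("barometric pressure must be positive")
  if (flow_ml_min <= 0) stop("chamber flow must be positive")
  structure(list(ta_c = ta_c, pb_mmhg = pb_mmhg, rh = rh,
                 flow_ml_min = flow_ml_min, chamber_ml = chamber_ml),
            class = "environment_record")
}

#' Animal record with body-temperature timepoints
#'
#' Body temperature (Tb) is measured sparsely (rectal probe at a handful of
#' protocol timepoints); [tb_at()] interpolates linearly between timepoints and
#' holds the end values constant outside their range.
#'
#' @param id animal identifier
#' @param group group label, one of `"ctrl"`, `"ncko_r"`, `"ncko_a"`, `"custom"`
#' @param mass_g body mass in grams
#' @param tb data frame with columns `time_s`, `tb_c` (rectal temperature, C)
#' @return an object of class `animal_record`
#' @export
animal_record <- function(id, group = "custom", mass_g = 25,
                          tb = data.frame(time_s = 0, tb_c = 37)) {
  group <- match.arg(group, GROUP_LABELS)
  if (mass_g <= 0) stop("body mass must be positive")
  stopifnot(is.data.frame(tb), all(c("time_s", "tb_c") %in% names(tb)))
  if (is.unsorted(tb$time_s, strictly = FALSE))
    stop("Tb timepoints must be time-ordered")
  structure(list(id = as.character(id), group = group, mass_g = mass_g,
                 tb = tb), class = "animal_record")
}

#' Interpolated body temperature at a time
#'
#' @param animal an [animal_record()]
#' @param time_s time(s) in seconds
#' @return Tb in degrees C, linearly interpolated, constant beyond the ends
#' @export
tb_at <- function(animal, time_s) {
  tb <- animal$tb
  if (nrow(tb) == 1L) return(rep(tb$tb_c, length(time_s)))
  stats::approx(tb$time_s, tb$tb_c, xout = time_s, rule = 2)$y
}

#' Calibration record
#'
#' The system is calibrated by injecting a known volume `v_k_ml` (typically
#' 0.25 ml) into the chamber; `p_k` is the mean pressure deflection that the
#' injection produces, in the same arbitrary units as the trace.
#'
#' @param v_k_ml injected calibration volume, ml
#' @param p_k mean calibration pressure deflection, trace units
#' @return an object of class `calibration_record`
#' @export
calibration_record <- function(v_k_ml = 0.25, p_k = 1) {
  if (v_k_ml <= 0) stop("calibration volume must be positive")
  if (p_k <= 0) stop("calibration deflection must be positive")
  structure(list(v_k_ml = v_k_ml, p_k = p_k), class = "calibration_record")
}

#' Protocol epoch table
#'
#' Epochs are half-open intervals `[start_s, end_s)` labelled with the gas
#' condition and its inspired O2 fraction. They must be time-ordered,
#' non-overlapping and (when a trace span is supplied) within the trace.
#'
#' @param label character vector of epoch labels
#' @param start_s,end_s epoch boundaries, seconds
#' @param fio2 inspired O2 fraction per epoch
#' @return data frame of class `epoch_table`
#' @export
epoch_table <- function(label, start_s, end_s,
                        fio2 = rep(0.21, length(label))) {
  ep <- data.frame(label = as.character(label), start_s = start_s,
                   end_s = end_s, fio2 = fio2, stringsAsFactors = FALSE)
  validate_epochs(ep)
  class(ep) <- c("epoch_table", "data.frame")
  ep
}

validate_epochs <- function(ep, span = NULL) {
  stopifnot(all(c("label", "start_s", "end_s", "fio2") %in% names(ep)))
  if (!all(ep$label %in% EPOCH_LABELS))
    stop("epoch labels must be one of: ", paste(EPOCH_LABELS, collapse = ", "))
  if (any(ep$end_s <= ep$start_s)) stop("epoch end must exceed epoch start")
  if (nrow(ep) > 1L) {
    o <- order(ep$start_s)
    if (!identical(o, seq_len(nrow(ep)))) stop("epochs must be time-ordered")
    if (any(ep$start_s[-1L] < ep$end_s[-nrow(ep)] - 1e-9))
      stop("epochs overlap")
  }
  if (!is.null(span)) {
    if (any(ep$start_s < -1e-9) || any(ep$end_s > span + 1e-9))
      stop("epochs extend beyond the trace span")
  }
  invisible(ep)
}

#' Pressure trace
#'
#' A uniformly sampled chamber-pressure signal together with the protocol
#' epochs, chamber environment and animal metadata.
#'
#' @param samples numeric vector of pressure deflections (arbitrary units)
#' @param sample_rate sampling rate, Hz
#' @param epochs an [epoch_table()] (may be empty)
#' @param environment an [environment_record()]
#' @param animal an [animal_record()]
#' @return an object of class `pressure_trace`
#' @export
pressure_trace <- function(samples, sample_rate, epochs = NULL,
                           environment = environment_record(),
                           animal = animal_record("a1")) {
  if (sample_rate <= 0) stop("sample rate must be positive")
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("trace samples must be finite")
  span <- length(samples) / sample_rate
  if (is.null(epochs))
    epochs <- epoch_table(character(), numeric(), numeric(), numeric())
  else validate_epochs(epochs, span = span)
  structure(list(samples = samples, sample_rate = sample_rate,
                 epochs = epochs, environment = environment, animal = animal),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples @ %g Hz (%.1f s), %d epoch(s), animal %s [%s]\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, nrow(x$epochs),
              x$animal$id, x$animal$group))
  invisible(x)
}

#' Duration of a pressure trace in seconds
#' @param trace a [pressure_trace()]
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sample_rate

#' Per-breath table
#'
#' One row per detected (or generated) breath with onset, end of inspiration
#' and offset times, inspiratory/expiratory/total durations, peak inspiratory
#' deflection `p_t` and tidal volume `v_t_ml` (NA until calibrated).
#'
#' @param breaths data frame with columns `onset_s`, `insp_end_s`, `offset_s`,
#'   `ti_s`, `te_s`, `ttot_s`, `p_t`, `v_t_ml`
#' @param animal optional [animal_record()]
#' @param provenance list of parameters used to produce the table
#' @return data frame of class `breath_table`
#' @export
breath_table <- function(breaths, animal = NULL, provenance = list()) {
  cols <- c("onset_s", "insp_end_s", "offset_s", "ti_s", "te_s", "ttot_s",
            "p_t", "v_t_ml")
  if (nrow(breaths)) {
    missing <- setdiff(cols, names(breaths))
    if (length(missing))
      stop("breath table missing columns: ", paste(missing, collapse = ", "))
    b <- breaths[, cols]
    if (any(b$onset_s >= b$insp_end_s) || any(b$insp_end_s >= b$offset_s))
      stop("breaths must satisfy onset < insp_end < offset")
    if (is.unsorted(b$onset_s)) stop("breaths must be time-ordered")
    if (any(b$onset_s[-1L] < b$offset_s[-nrow(b)] - 1e-9))
      stop("breaths overlap")
    if (any(abs(b$ti_s + b$te_s - b$ttot_s) > 1e-6))
      stop("ti + te must equal ttot")
    if (any(b$p_t < 0)) stop("peak deflection must be non-negative")
  } else {
    b <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)), cols))
  }
  attr(b, "animal") <- animal
  attr(b, "provenance") <- provenance
  class(b) <- c("breath_table", "data.frame")
  b
}

#' @export
print.breath_table <- function(x, ...) {
  cat(sprintf("<breath_table> %d breaths", nrow(x)))
  if (nrow(x)) cat(sprintf(" spanning %.2f-%.2f s, median fR %.1f /min",
                           x$onset_s[1L], x$offset_s[nrow(x)],
                           60 / stats::median(x$ttot_s)))
  cat("\n")
  NextMethod()
}

#' Respiratory event table
#'
#' @param kind event kind, `"SA"`, `"sigh"` or `"PSA"`
#' @param time_s event time, s (breath onset for sighs, expected-onset of the
#'   first missing breath for apneas)
#' @param duration_s apnea pause duration, s (NA for sighs)
#' @param missing_cycles rounded number of missing breath cycles (NA for sighs)
#' @param sigh_ref id of the linked sigh (PSA only)
#' @param id event identifier
#' @return data frame of class `event_table`
#' @export
event_table <- function(kind = character(), time_s = numeric(),
                        duration_s = rep(NA_real_, length(kind)),
                        missing_cycles = rep(NA_real_, length(kind)),
                        sigh_ref = rep(NA_integer_, length(kind)),
                        id = seq_along(kind)) {
  if (!all(kind %in% c("SA", "sigh", "PSA"))) stop("unknown event kind")
  ev <- data.frame(id = as.integer(id), kind = kind, time_s = time_s,
                   duration_s = duration_s, missing_cycles = missing_cycles,
                   sigh_ref = as.integer(sigh_ref), stringsAsFactors = FALSE)
  if (any(ev$kind == "PSA" & is.na(ev$sigh_ref)))
    stop("every PSA must carry a sigh reference")
  if (any(ev$kind %in% c("SA", "PSA") & !(ev$duration_s > 0)))
    stop("apnea durations must be positive")
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Gas-fraction trace for calorimetry
#'
#' Inflow/outflow O2 and CO2 fractions plus the excurrent flow through the
#' chamber. Fractions may be scalars (epoch means) or equal-length vectors.
#'
#' @param fr_e excurrent flow rate, ml/min
#' @param fio2,feo2,fico2,feco2 gas fractions in \[0, 1\]
#' @return an object of class `gas_trace`
#' @export
gas_trace <- function(fr_e, fio2, feo2, fico2 = 0.0004, feco2 = fico2) {
  fr <- c(fio2, feo2, fico2, feco2)
  if (any(fr < 0 | fr > 1)) stop("gas fractions must lie in [0, 1]")
  if (any(fr_e <= 0)) stop("excurrent flow must be positive")
  structure(list(fr_e = fr_e, fio2 = fio2, feo2 = feo2,
                 fico2 = fico2, feco2 = feco2), class = "gas_trace")
}

#' Named 3-D landmark set
#'
#' Landmarks live in a right-handed skull frame (x: left to right,
#' y: posterior to anterior, z: inferior to superior), in mm.
#'
#' @param points data frame with columns `name`, `x_mm`, `y_mm`, `z_mm`
#' @param animal optional animal id
#' @param replicate optional replicate index (rater placement round)
#' @return data frame of class `landmark_set`
#' @export
landmark_set <- function(points, animal = NA_character_, replicate = NA_integer_) {
  stopifnot(all(c("name", "x_mm", "y_mm", "z_mm") %in% names(points)))
  if (anyDuplicated(points$name)) stop("landmark names must be unique")
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(xyz))) stop("landmark coordinates must be finite")
  p <- points[, c("name", "x_mm", "y_mm", "z_mm")]
  attr(p, "animal") <- animal
  attr(p, "replicate") <- replicate
  class(p) <- c("landmark_set", "data.frame")
  p
}

landmark_xyz <- function(set, name) {
  i <- match(name, set$name)
  if (is.na(i)) stop("landmark not found: ", name)
  c(set$x_mm[i], set$y_mm[i], set$z_mm[i])
}

#' Long-format cohort table
#'
#' One value per (animal, group, condition, variable) combination.
#'
#' @param records data frame with columns `animal`, `group`, `condition`,
#'   `variable`, `value`
#' @param units optional named character vector of units per variable
#' @return data frame of class `cohort_table`
#' @export
cohort_table <- function(records, units = character()) {
  stopifnot(all(c("animal", "group", "condition", "variable", "value") %in%
                  names(records)))
  key <- paste(records$animal, records$condition, records$variable)
  if (anyDuplicated(key))
    stop("one value per (animal, condition, variable) is required")
  attr(records, "units") <- units
  class(records) <- c("cohort_table", "data.frame")
  records
}

#' Metabolite concentration table
#'
#' @param concentrations animal x metabolite numeric matrix, uM
#' @param groups group label per animal (rownames order)
#' @return an object of class `metabolite_table`
#' @export
metabolite_table <- function(concentrations, groups) {
  m <- as.matrix(concentrations)
  if (any(m < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  if (length(groups) != nrow(m)) stop("one group label per animal is required")
  if (anyNA(groups)) stop("group labels must be complete")
  structure(list(concentrations = m, groups = as.character(groups)),
            class = "metabolite_table")
}

# ---- file I/O ---------------------------------------------------------------

#' Read a pressure trace from delimited text plus a metadata sidecar
#'
#' The trace file must have columns `time_s` and `pressure`; the YAML (or
#' JSON-compatible) sidecar supplies `sample_rate_hz`, `epochs`, `environment`
#' and `animal`. Sampling uniformity is checked: the maximum deviation of the
#' time column from a uniform grid must be below half a sample period.
#'
#' @param path path to the delimited trace file
#' @param meta_path path to the YAML metadata sidecar
#' @return a [pressure_trace()]
#' @export
read_pressure_trace <- function(path, meta_path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure") %in% names(d)))
    stop("trace file must have columns time_s,pressure: ", path)
  tt <- d$time_s
  if (any(diff(tt) <= 0))
    stop("non-monotone time column in ", path)
  meta <- yaml::read_yaml(meta_path)
  for (key in c("sample_rate_hz", "environment", "animal")) {
    if (is.null(meta[[key]])) stop("metadata missing required key: ", key)
  }
  fs <- meta$sample_rate_hz
  grid <- tt[1L] + (seq_along(tt) - 1L) / fs
  if (max(abs(tt - grid)) >= 0.5 / fs)
    stop("time column deviates from uniform sampling at ", fs, " Hz")
  envm <- meta$environment
  env <- environment_record(ta_c = envm$ta_c, pb_mmhg = envm$pb_mmhg,
                            rh = envm$rh, flow_ml_min = envm$flow_ml_min,
                            chamber_ml = envm$chamber_ml)
  am <- meta$animal
  tb <- if (!is.null(am$tb)) {
    do.call(rbind, lapply(am$tb, function(r)
      data.frame(time_s = r$time_s, tb_c = r$tb_c)))
  } else data.frame(time_s = 0, tb_c = 37)
  animal <- animal_record(am$id, am$group, am$mass_g, tb)
  epochs <- if (length(meta$epochs)) {
    e <- do.call(rbind, lapply(meta$epochs, function(r)
      data.frame(label = r$label, start_s = r$start_s, end_s = r$end_s,
                 fio2 = r$fio2, stringsAsFactors = FALSE)))
    epoch_table(e$label, e$start_s, e$end_s, e$fio2)
  } else NULL
  pressure_trace(d$pressure, fs, epochs, env, animal)
}

#' Write a pressure trace and its metadata sidecar
#'
#' @param trace a [pressure_trace()]
#' @param path output path for the trace CSV
#' @param meta_path output path for the YAML sidecar
#' @return invisibly, `path`
#' @export
write_pressure_trace <- function(trace, path, meta_path) {
  n <- length(trace$samples)
  d <- data.frame(time_s = (seq_len(n) - 1L) / trace$sample_rate,
                  pressure = trace$samples)
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  env <- trace$environment
  an <- trace$animal
  meta <- list(
    sample_rate_hz = trace$sample_rate,
    epochs = lapply(seq_len(nrow(trace$epochs)), function(i)
      list(label = trace$epochs$label[i], start_s = trace$epochs$start_s[i],
           end_s = trace$epochs$end_s[i], fio2 = trace$epochs$fio2[i])),
    environment = list(ta_c = env$ta_c, pb_mmhg = env$pb_mmhg, rh = env$rh,
                       flow_ml_min = env$flow_ml_min,
                       chamber_ml = env$chamber_ml),
    animal = list(id = an$id, group = an$group, mass_g = an$mass_g,
                  tb = lapply(seq_len(nrow(an$tb)), function(i)
                    list(time_s = an$tb$time_s[i], tb_c = an$tb$tb_c[i]))))
  yaml::write_yaml(meta, meta_path, precision = 15)
  invisible(path)
}

#' Write / read a breath table as TSV
#'
#' The TSV carries one row per breath and a header naming each column with its
#' unit; float round-trips are lossless to well below 1e-9.
#'
#' @param table a [breath_table()]
#' @param path output path
#' @return invisibly, `path` (writer); a [breath_table()] (reader)
#' @export
write_breath_table <- function(table, path) {
  df <- as.data.frame(table)
  out <- tryCatch(
    utils::write.table(format(df, digits = 17, trim = TRUE), path,
                       sep = "\t", row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed to write breath table to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' @rdname write_breath_table
#' @export
read_breath_table <- function(path) {
  df <- tryCatch(utils::read.delim(path),
                 error = function(e) stop("failed to read breath table from ",
                                          path, ": ", conditionMessage(e)))
  breath_table(df)
}

#' Write / read a respiratory event table as TSV
#' @param events an [event_table()]
#' @param path output path
#' @export
write_events <- function(events, path) {
  utils::write.table(format(as.data.frame(events), digits = 17, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, na.strings = c("NA", ""))
  event_table(kind = df$kind, time_s = df$time_s, duration_s = df$duration_s,
              missing_cycles = df$missing_cycles, sigh_ref = df$sigh_ref,
              id = df$id)
}

#' Read / write a landmark set as CSV (`name,x_mm,y_mm,z_mm`)
#'
#' @param path CSV path
#' @return a [landmark_set()]
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x_mm", "y_mm", "z_mm") %in% names(df)))
    stop("landmark file must have columns name,x_mm,y_mm,z_mm: ", path)
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric coordinate in column ", col, " of ", path)
    df[[col]] <- v
  }
  if (anyDuplicated(df$name))
    stop("duplicate landmark name in ", path, ": ",
         df$name[duplicated(df$name)][1L])
  landmark_set(df)
}

#' @rdname read_landmarks
#' @param set a [landmark_set()]
#' @export
write_landmarks <- function(set, path) {
  utils::write.csv(format(as.data.frame(set), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
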