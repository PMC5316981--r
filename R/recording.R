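#' High-resolution colonic manometry recording
#'
#' Container for a multichannel intraluminal pressure recording: a
#' sensors-by-samples matrix of pressures (mmHg) from a linear catheter with
#' uniformly spaced solid-state sensors, plus the metadata needed to interpret
#' it (sampling rate, sensor spacing, catheter tip position, per-sensor
#' functional mask, recording phases).
#'
#' Sensors are indexed 1..n distal to proximal: sensor 1 (P1) is closest to
#' the anal verge, sensor `n_sensors` (P36 on the standard 36-sensor probe)
#' is most proximal and sits at `tip_position` cm from the anal verge.
#' Time is in seconds from recording start; all windows are half-open
#' `[start, end)`.
#'
#' @param pressures numeric matrix, `n_sensors` rows by samples columns, mmHg.
#' @param sampling_rate samples per second (Hz).
#' @param sensor_spacing distance between adjacent sensors, cm.
#' @param tip_position position of the most proximal sensor, cm from the anal
#'   verge.
#' @param functional_mask logical vector, one entry per sensor; `FALSE` marks a
#'   malfunctioning sensor that is ignored by all detectors.
#' @param phases tibble with columns `label` (one of `"baseline"`,
#'   `"meal_intake"`, `"postprandial"`, `"sphincter_pullback"`), `start_s`,
#'   `end_s`. Labels other than `sphincter_pullback` must be unique.
#' @param subject_id free-text subject identifier.
#' @param group subject group, one of `"constipation"`, `"healthy_control"`,
#'   `"patient_control"`, `"synthetic"`.
#'
#' @return An object of class `hrcm_recording`.
#' @examples
#' rec <- recording(matrix(0, 36, 600), sampling_rate = 10, tip_position = 85)
#' recording_duration(rec)
#' sensor_position(rec, 36)
#' @export
recording <- function(pressures, sampling_rate = 10, sensor_spacing = 1,
                      tip_position = 85, functional_mask = NULL,
                      phases = NULL, subject_id = "anon",
                      group = c("synthetic", "constipation", "healthy_control",
                                "patient_control")) {
  pressures <- as.matrix(pressures)
  storage.mode(pressures) <- "double"
  n <- nrow(pressures)
  if (is.null(functional_mask)) functional_mask <- rep(TRUE, n)
  if (is.null(phases)) {
    phases <- tibble::tibble(label = character(), start_s = double(),
                             end_s = double())
  }
  rec <- structure(
    list(pressures = pressures,
         sampling_rate = sampling_rate,
         sensor_spacing = sensor_spacing,
         n_sensors = n,
         tip_position = tip_position,
         functional_mask = functional_mask,
         phases = tibble::as_tibble(phases),
         subject_id = subject_id,
         group = match.arg(group)),
    class = "hrcm_recording")
  validate_recording(rec)
}

#' Validate an `hrcm_recording`
#'
#' Checks the structural invariants: row count matches `n_sensors`, positive
#' sampling rate, mask length, and that every phase window lies inside
#' `[0, duration]` with `start_s < end_s`.
#'
#' @param rec an `hrcm_recording`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "hrcm_recording"))
  if (nrow(rec$pressures) != rec$n_sensors)
    stop("pressures must have exactly n_sensors (", rec$n_sensors, ") rows, got ",
         nrow(rec$pressures), call. = FALSE)
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  if (length(rec$functional_mask) != rec$n_sensors)
    stop("functional_mask must have one entry per sensor", call. = FALSE)
  dur <- recording_duration(rec)
  ph <- rec$phases
  if (nrow(ph)) {
    if (any(ph$start_s >= ph$end_s))
      stop("phase windows must have start_s < end_s", call. = FALSE)
    if (any(ph$start_s < 0) || any(ph$end_s > dur + 1e-9))
      stop("phase windows must lie within [0, duration]", call. = FALSE)
    bad <- setdiff(ph$label, c("baseline", "meal_intake", "postprandial",
                               "sphincter_pullback"))
    if (length(bad))
      stop("unknown phase label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    non_sp <- ph$label[ph$label != "sphincter_pullback"]
    if (anyDuplicated(non_sp))
      stop("phase labels must be unique (except sphincter_pullback)",
           call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.hrcm_recording <- function(x, ...) {
  cat("<hrcm_recording> ", x$subject_id, " (", x$group, ")\n", sep = "")
  cat("  ", x$n_sensors, " sensors x ", ncol(x$pressures), " samples @ ",
      x$sampling_rate, " Hz (", round(recording_duration(x), 1), " s)\n",
      sep = "")
  cat("  spacing ", x$sensor_spacing, " cm, tip at ", x$tip_position,
      " cm from anal verge, ", sum(!x$functional_mask),
      " malfunctioning sensor(s)\n", sep = "")
  if (nrow(x$phases))
    cat("  phases: ", paste0(x$phases$label, " [", x$phases$start_s, ", ",
                             x$phases$end_s, ")", collapse = "; "), "\n",
        sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `hrcm_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$pressures) / rec$sampling_rate

#' Time vector of a recording
#' @param rec an `hrcm_recording`.
#' @return numeric vector of sample times (s), starting at 0.
#' @export
recording_times <- function(rec) {
  (seq_len(ncol(rec$pressures)) - 1) / rec$sampling_rate
}

#' Position of a sensor along the colon
#'
#' The catheter tip (most proximal sensor) sits at `tip_position` cm from the
#' anal verge; sensor positions decrease distally by `sensor_spacing` cm per
#' sensor: `position = tip_position - (n_sensors - index) * sensor_spacing`.
#'
#' @param rec an `hrcm_recording`.
#' @param sensor_index integer vector of sensor indices in `1..n_sensors`.
#' @return positions in cm from the anal verge.
#' @examples
#' rec <- recording(matrix(0, 36, 10), tip_position = 85)
#' sensor_position(rec, c(1, 36)) # 50, 85
#' @export
sensor_position <- function(rec, sensor_index) {
  if (any(sensor_index < 1 | sensor_index > rec$n_sensors))
    stop("sensor_index out of range 1..", rec$n_sensors, call. = FALSE)
  rec$tip_position - (rec$n_sensors - sensor_index) * rec$sensor_spacing
}

#' Identify internal anal sphincter channels
#'
#' When the recording carries a `sphincter_pullback` phase, the one or two
#' most distal functional channels whose resting tone (median pressure)
#' exceeds `tone_min` are taken to sit at the internal anal sphincter. These
#' channels are used for artifact screening and relaxation association and
#' are excluded from colonic motor-pattern detection.
#'
#' @param rec an `hrcm_recording`.
#' @param tone_min minimum resting tone (mmHg) for a channel to qualify.
#' @return integer vector of sphincter channel indices (possibly empty).
#' @export
sphincter_channels <- function(rec, tone_min = 20) {
  if (!nrow(rec$phases) || !any(rec$phases$label == "sphincter_pullback"))
    return(integer())
  cand <- which(rec$functional_mask)[1:2]
  cand <- cand[!is.na(cand)]
  tone <- apply(rec$pressures[cand, , drop = FALSE], 1, stats::median,
                na.rm = TRUE)
  cand[tone > tone_min]
}

#' Build a phase-window tibble
#'
#' @param label character vector of phase labels.
#' @param start_s,end_s window bounds in seconds (half-open).
#' @return tibble with columns `label`, `start_s`, `end_s`.
#' @export
phase_windows <- function(label, start_s, end_s) {
  tibble::tibble(label = label, start_s = as.double(start_s),
                 end_s = as.double(end_s))
}
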