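#' Classify a candidate multi-sensor event
#'
#' Applies the taxonomy in fixed decision order, making the classes mutually
#' exclusive and exhaustive over candidates:
#' 1. a single-sensor candidate is an isolated pressure transient;
#' 2. at least `hapw_min_sensors` members at or above `hapw_amplitude` with a
#'    determinate velocity is an HAPW;
#' 3. a simultaneous front lasting at least `min_spw_duration_s` and spanning
#'    at least `min_spw_span_cm` is an SPW;
#' 4. a determinate velocity over at least `apw_min_sensors` adjacent sensors
#'    is an APW (antegrade, velocity > 0) or RPW (retrograde);
#' 5. anything else falls back to isolated transients, one per member.
#'
#' @param candidate tibble of member transients (one candidate).
#' @param velocity list from [estimate_velocity()].
#' @param thresholds a [classification_thresholds()] list.
#' @param sensor_spacing cm.
#' @return character: `"SPW"`, `"APW"`, `"RPW"`, `"HAPW"`,
#'   `"isolated_transient"` (single member), or `"fallback"` (rule 5:
#'   dissolve into per-member isolated transients).
#' @export
classify_event <- function(candidate, velocity,
                           thresholds = classification_thresholds(),
                           sensor_spacing = 1) {
  th <- thresholds
  sensors <- unique(candidate$sensor)
  if (length(sensors) == 1L) return("isolated_transient")
  per_sensor_max <- tapply(candidate$amplitude, candidate$sensor, max)
  determinate <- !isTRUE(velocity$simultaneous) && !isTRUE(velocity$undefined)
  if (sum(per_sensor_max >= th$hapw_amplitude) >= th$hapw_min_sensors &&
      determinate)
    return("HAPW")
  dur <- stats::median(candidate$offset_s - candidate$onset_s)
  span <- diff(range(sensors)) * sensor_spacing
  if (isTRUE(velocity$simultaneous) && dur >= th$min_spw_duration_s &&
      span >= th$min_spw_span_cm)
    return("SPW")
  if (determinate && length(sensors) >= th$apw_min_sensors)
    return(if (velocity$velocity > 0) "APW" else "RPW")
  "fallback"
}

#' Measure the summary parameters of a classified event
#'
#' Duration is the median over member sensors of (offset - onset); span is
#' (last member sensor - first member sensor) x spacing, in cm; mean
#' amplitude is the baseline-subtracted pressure at the event's temporal
#' center averaged across member sensors (the "cursor at the center"
#' convention); max amplitude is the largest member amplitude.
#'
#' @param members tibble of member transients.
#' @param rec an `hrcm_recording`.
#' @param thresholds a [classification_thresholds()] list.
#' @param detrended optional precomputed [detrended_matrix()].
#' @return one-row tibble: `onset_s`, `offset_s`, `peak_s`, `duration_s`,
#'   `span_cm`, `first_sensor`, `last_sensor`, `n_sensors`,
#'   `amplitude_mean`, `amplitude_max`.
#' @export
event_parameters <- function(members, rec,
                             thresholds = classification_thresholds(),
                             detrended = NULL) {
  fs <- rec$sampling_rate
  if (is.null(detrended)) detrended <- detrended_matrix(rec, thresholds)
  onset <- min(members$onset_s)
  offset <- max(members$offset_s)
  center <- (onset + offset) / 2
  ci <- pmin(max(1L, round(center * fs) + 1L), ncol(rec$pressures))
  sensors <- sort(unique(members$sensor))
  amp_center <- detrended[sensors, ci]
  tibble::tibble(
    onset_s = onset, offset_s = offset,
    peak_s = stats::median(members$peak_s),
    duration_s = stats::median(members$offset_s - members$onset_s),
    span_cm = diff(range(sensors)) * rec$sensor_spacing,
    first_sensor = sensors[1], last_sensor = sensors[length(sensors)],
    n_sensors = length(sensors),
    amplitude_mean = mean(amp_center),
    amplitude_max = max(members$amplitude))
}

#' Detect and classify all motor-pattern events in a recording
#'
#' The full event pipeline: build the artifact exclusion mask from the
#' annotation log, detect per-sensor transients, chain them into candidate
#' events, estimate each candidate's propagation velocity, screen global
#' simultaneous pressurizations against the sphincter
#' pressurization-versus-relaxation rule (or the cough-morphology fallback),
#' classify surviving candidates into SPW / APW / RPW / HAPW / isolated
#' pressure transients, fill in duration, span and amplitudes, and attach
#' sphincter-relaxation and gas-expulsion associations.
#'
#' @param rec an `hrcm_recording`.
#' @param annotations optional annotation tibble ([annotation_log()]).
#' @param thresholds a [classification_thresholds()] list.
#' @param mask_artifacts artifact screening mode: `"annotations"` (mask
#'   annotated intervals), `"signal"` (sphincter/morphology rule on global
#'   pressurizations), `"both"`, or `"none"`.
#' @param gas_window_s window for gas-expulsion association, s.
#' @return tibble of classified events, one row per event, with columns
#'   `kind`, `onset_s`, `duration_s`, `span_cm`, `velocity` (signed cm/s,
#'   `NA` when simultaneous), `simultaneous`, `amplitude_mean`,
#'   `amplitude_max`, `first_sensor`, `last_sensor`, `n_sensors`,
#'   `sphincter_relaxation`, `gas_associated`. The per-sensor transient
#'   table and the exclusion mask are attached as attributes `"transients"`
#'   and `"mask"`.
#' @export
detect_events <- function(rec, annotations = NULL,
                          thresholds = classification_thresholds(),
                          mask_artifacts = c("annotations", "signal", "both",
                                             "none"),
                          gas_window_s = 10) {
  mask_artifacts <- match.arg(mask_artifacts)
  th <- thresholds
  mask <- NULL
  if (mask_artifacts %in% c("annotations", "both") && !is.null(annotations))
    mask <- exclusion_mask(rec, screen_annotations(annotations))
  dmat <- detrended_matrix(rec, th)
  trans <- detect_transients(rec, th, mask, detrended = dmat)
  trans <- group_transients(trans, th)
  n_analyzed <- length(setdiff(which(rec$functional_mask),
                               sphincter_channels(rec)))
  rows <- list()
  for (cid in unique(trans$candidate)) {
    members <- trans[trans$candidate == cid, ]
    vel <- estimate_velocity(members, rec$sensor_spacing, th)
    # screen global simultaneous pressurizations (cough / body shift) before
    # classification, so an abdominal event can never enter the taxonomy
    if (mask_artifacts %in% c("signal", "both") &&
        (isTRUE(vel$simultaneous) || isTRUE(vel$undefined)) &&
        length(unique(members$sensor)) >= 0.6 * n_analyzed) {
      par0 <- event_parameters(members, rec, th, detrended = dmat)
      verdict <- classify_global_pressurization(
        dplyr::mutate(par0, simultaneous = TRUE), rec)
      if (verdict == "abdominal") next
    }
    kind <- classify_event(members, vel, th, rec$sensor_spacing)
    if (kind == "fallback") {
      for (i in seq_len(nrow(members))) {
        par <- event_parameters(members[i, ], rec, th, detrended = dmat)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(kind = "isolated_transient", velocity = NA_real_,
                         simultaneous = FALSE), par)
      }
      next
    }
    par <- event_parameters(members, rec, th, detrended = dmat)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(kind = kind,
                     velocity = if (isTRUE(vel$simultaneous)) NA_real_ else
                       vel$velocity,
                     simultaneous = isTRUE(vel$simultaneous)), par)
  }
  events <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(kind = character(), velocity = double(),
                   simultaneous = logical(), onset_s = double(),
                   offset_s = double(), peak_s = double(),
                   duration_s = double(), span_cm = double(),
                   first_sensor = integer(), last_sensor = integer(),
                   n_sensors = integer(), amplitude_mean = double(),
                   amplitude_max = double())
  events <- dplyr::arrange(events, .data$onset_s)
  events <- drop_connected_transients(events)
  events <- sphincter_association(events, rec)
  events <- gas_association(events, annotations, gas_window_s)
  attr(events, "transients") <- trans
  attr(events, "mask") <- mask
  events
}

# An isolated pressure transient is by definition NOT connected to other
# pressure changes: single-sensor events falling inside the time-sensor
# footprint of a multi-sensor wave (e.g. the superimposed peaks on an SPW
# decay limb) are part of that wave, not separate events.
drop_connected_transients <- function(events) {
  iso <- events$kind == "isolated_transient"
  if (!any(iso) || all(iso)) return(events)
  multi <- events[!iso, , drop = FALSE]
  drop <- vapply(which(iso), function(i) {
    any(events$first_sensor[i] >= multi$first_sensor - 1L &
          events$first_sensor[i] <= multi$last_sensor + 1L &
          events$onset_s[i] >= multi$onset_s - 1 &
          events$onset_s[i] <= multi$offset_s + 1)
  }, logical(1))
  if (!any(drop)) return(events)
  events[-which(iso)[drop], , drop = FALSE]
}

#' Associate SPWs with internal anal sphincter relaxation
#'
#' For each SPW, reports `"yes"` when the sphincter pressure falls at least
#' 20% below its local resting tone anywhere in `[onset - 5 s, offset]`
#' (relaxation precedes the arriving wave), `"no"` otherwise, and
#' `"undetermined"` when the recording has no sphincter channel (no
#' `sphincter_pullback` phase). Non-SPW events are `"undetermined"`.
#'
#' @param events event tibble from [detect_events()].
#' @param rec an `hrcm_recording`.
#' @param dip_frac relative relaxation criterion.
#' @return `events` with a `sphincter_relaxation` column.
#' @export
sphincter_association <- function(events, rec, dip_frac = 0.2) {
  sph <- sphincter_channels(rec)
  events$sphincter_relaxation <- "undetermined"
  if (!length(sph) || !nrow(events)) return(events)
  fs <- rec$sampling_rate
  trace <- colMeans(rec$pressures[sph, , drop = FALSE])
  idx <- function(t) pmin(pmax(1L, round(t * fs) + 1L), length(trace))
  for (i in which(events$kind == "SPW")) {
    tone <- stats::median(trace[idx(events$onset_s[i] - 40):
                                  idx(events$onset_s[i] - 8)])
    win <- trace[idx(events$onset_s[i] - 5):idx(events$offset_s[i])]
    events$sphincter_relaxation[i] <-
      if (min(win) <= tone * (1 - dip_frac)) "yes" else "no"
  }
  events
}

#' Associate SPWs with reported gas expulsion
#'
#' Flags each SPW whose window (padded by `window_s`) contains a
#' gas-expulsion annotation, and computes the two-way summary: the fraction
#' of SPWs that were gas-associated, and the converse check - the fraction
#' of gas-expulsion reports with a matching SPW.
#'
#' @param events event tibble.
#' @param annotations annotation tibble (or `NULL`).
#' @param window_s association half-window, s.
#' @return `events` with a logical `gas_associated` column and an attribute
#'   `"gas_summary"` (list with `frac_spw_gas`, `frac_gas_with_spw`,
#'   `n_spw`, `n_gas`).
#' @export
gas_association <- function(events, annotations = NULL, window_s = 10) {
  events$gas_associated <- FALSE
  gas <- if (!is.null(annotations) && nrow(annotations))
    annotations$time_s[annotations$kind == "gas_expulsion"] else numeric()
  spw <- which(events$kind == "SPW")
  gas_hit <- rep(FALSE, length(gas))
  for (i in spw) {
    lo <- events$onset_s[i] - window_s
    hi <- events$offset_s[i] + window_s
    hits <- gas >= lo & gas <= hi
    events$gas_associated[i] <- any(hits)
    gas_hit <- gas_hit | hits
  }
  attr(events, "gas_summary") <- list(
    frac_spw_gas = if (length(spw)) mean(events$gas_associated[spw]) else NA,
    frac_gas_with_spw = if (length(gas)) mean(gas_hit) else NA,
    n_spw = length(spw), n_gas = length(gas))
  events
}
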