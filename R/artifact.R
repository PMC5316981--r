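#' Artifact intervals from the annotation log
#'
#' Converts contemporaneous observer annotations of abdominal-pressure events
#' into exclusion intervals: each cough/talk/drink annotation becomes
#' `[t - pad_s, t + pad_s)`, each body shift or repositioning becomes
#' `[t - shift_pad_s, t + shift_pad_s)`. Gas expulsion is a colonic event
#' (it accompanies simultaneous pressure waves) and never becomes an
#' artifact; neither do bowel urge or meal markers.
#'
#' @param log annotation tibble from [annotation_log()].
#' @param pad_s half-width around cough/talk/drink annotations, s.
#' @param shift_pad_s half-width around body-shift/reposition annotations, s.
#' @return tibble with columns `start_s`, `end_s`, `kind`, `source`
#'   (`"annotation"`), `confidence`.
#' @export
screen_annotations <- function(log, pad_s = 3, shift_pad_s = 10) {
  if (is.null(log) || !nrow(log))
    return(tibble::tibble(start_s = double(), end_s = double(),
                          kind = character(), source = character(),
                          confidence = double()))
  log |>
    dplyr::filter(.data$kind %in% c("cough", "talk", "body_shift", "drink",
                                    "reposition")) |>
    dplyr::mutate(
      pad = ifelse(.data$kind %in% c("body_shift", "reposition"),
                   shift_pad_s, pad_s),
      start_s = pmax(0, .data$time_s - .data$pad),
      end_s = .data$time_s + .data$pad,
      source = "annotation", confidence = 1) |>
    dplyr::select("start_s", "end_s", "kind", "source", "confidence")
}

#' Build a boolean exclusion mask over recording time
#'
#' Marks every sample inside any artifact interval. Overlapping intervals
#' merge naturally; masking is idempotent and order-independent. Downstream
#' detectors drop events whose onset is masked, and masked time is removed
#' from the denominators of per-time metrics.
#'
#' @param rec an `hrcm_recording`.
#' @param intervals tibble with `start_s`, `end_s` (from
#'   [screen_annotations()] or hand-built).
#' @return logical vector, one entry per sample; `TRUE` = excluded.
#' @export
exclusion_mask <- function(rec, intervals) {
  n <- ncol(rec$pressures)
  mask <- rep(FALSE, n)
  if (is.null(intervals) || !nrow(intervals)) return(mask)
  fs <- rec$sampling_rate
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(intervals$end_s[i] * fs))
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  mask
}

#' Seconds of unmasked time within a window
#' @param mask logical exclusion mask (or `NULL` for none).
#' @param sampling_rate Hz.
#' @param from_s,to_s half-open window, s.
#' @return unmasked seconds.
#' @export
unmasked_seconds <- function(mask, sampling_rate, from_s, to_s) {
  total <- to_s - from_s
  if (is.null(mask)) return(total)
  i0 <- floor(from_s * sampling_rate) + 1L
  i1 <- min(length(mask), ceiling(to_s * sampling_rate))
  if (i0 > i1) return(0)
  total - sum(mask[i0:i1]) / sampling_rate
}

#' Classify a global pressurization as colonic or abdominal
#'
#' Distinguishes a genuine simultaneous pressure wave from an
#' abdominal-pressure event (cough, body shift). The discriminating
#' physiology: coughs and body movements pressurize the internal anal
#' sphincter, whereas an approaching SPW is preceded by sphincter
#' relaxation. With a sphincter channel available, a sphincter rise of at
#' least `rise_mmHg` during the event is ruled abdominal; a dip to 20% or
#' more below the local resting tone starting at or before the event's
#' arrival is ruled colonic; otherwise undetermined. Without a sphincter
#' channel a morphology fallback is used: duration under 2.5 s with rise
#' time under 1 s (a cough signature, shorter than any SPW) is abdominal,
#' anything else colonic.
#'
#' @param event one-row tibble with `onset_s`, `offset_s`, `peak_s` and
#'   logical `simultaneous`; the event must span most sensors with
#'   simultaneous onset.
#' @param rec an `hrcm_recording`.
#' @param rise_mmHg sphincter pressurization criterion, mmHg.
#' @param dip_frac relative sphincter relaxation criterion.
#' @return `"colonic"`, `"abdominal"` or `"undetermined"`.
#' @export
classify_global_pressurization <- function(event, rec, rise_mmHg = 5,
                                           dip_frac = 0.2) {
  if (!isTRUE(event$simultaneous))
    stop("event must have simultaneous onset across sensors", call. = FALSE)
  sph <- sphincter_channels(rec)
  fs <- rec$sampling_rate
  idx <- function(t) pmin(pmax(1L, round(t * fs) + 1L), ncol(rec$pressures))
  if (length(sph)) {
    trace <- colMeans(rec$pressures[sph, , drop = FALSE])
    tone <- stats::median(trace[idx(event$onset_s - 40):idx(event$onset_s - 8)])
    during <- trace[idx(event$onset_s):idx(event$offset_s)]
    lead <- trace[idx(event$onset_s - 5):idx(event$offset_s)]
    if (max(during) - tone >= rise_mmHg) return("abdominal")
    if (min(lead) <= tone * (1 - dip_frac)) return("colonic")
    return("undetermined")
  }
  dur <- event$offset_s - event$onset_s
  rise <- event$peak_s - event$onset_s
  if (dur < 2.5 && rise < 1) "abdominal" else "colonic"
}
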