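#' Classification thresholds for motor-pattern detection
#'
#' The numeric criteria of the pattern taxonomy. Defaults are the standard
#' published criteria: a simultaneous pressure wave needs at least 2.5 s
#' duration and 5 mmHg amplitude appearing simultaneously over most of the
#' array; propagation velocity can be resolved only up to ~7 cm/s on a 1-cm
#' array, so fitted velocities beyond that bound are reported as
#' simultaneous; a high-amplitude propagating wave reaches at least 100 mmHg
#' in at least 3 sensors; antegrade/retrograde waves need 3 or more adjacent
#' sensors.
#'
#' @param min_amplitude minimum transient amplitude above baseline, mmHg.
#' @param min_spw_duration_s minimum SPW duration, s.
#' @param simultaneity_velocity velocity resolution bound, cm/s; faster
#'   fitted fronts are reported as simultaneous.
#' @param hapw_amplitude HAPW amplitude criterion, mmHg.
#' @param hapw_min_sensors minimum sensors at `hapw_amplitude` for an HAPW.
#' @param apw_min_sensors minimum adjacent sensors for a propagating wave.
#' @param min_spw_span_cm minimum spatial span of an SPW, cm ("most or all
#'   sensors"; 14 cm is the smallest span observed for real SPWs).
#' @param onset_group_window_s maximum onset gap between adjacent sensors
#'   chained into one candidate event, s.
#' @param merge_gap_s transients on one sensor closer than this are merged, s.
#' @param min_transient_duration_s minimum transient width at the 25%-of-peak
#'   level, s; rejects single-sample noise excursions.
#' @param smooth_s moving-average pre-smoother width, s.
#' @param baseline_window_s rolling-baseline window, s.
#' @return a named list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(min_amplitude = 5,
                                      min_spw_duration_s = 2.5,
                                      simultaneity_velocity = 7,
                                      hapw_amplitude = 100,
                                      hapw_min_sensors = 3,
                                      apw_min_sensors = 3,
                                      min_spw_span_cm = 14,
                                      onset_group_window_s = 2,
                                      merge_gap_s = 2,
                                      min_transient_duration_s = 0.5,
                                      smooth_s = 0.5,
                                      baseline_window_s = 60) {
  th <- as.list(environment())
  stopifnot(all(unlist(th[1:9]) > 0),
            hapw_amplitude > min_amplitude)
  structure(th, class = "classification_thresholds")
}

#' Rolling-percentile pressure baseline
#'
#' Estimates the slowly varying baseline of a single-sensor pressure trace as
#' a rolling 10th percentile over `window_s`-second windows (evaluated on a
#' 1-s grid and interpolated). Transients shorter than about half the window
#' leave the baseline essentially untouched; slow drifts are tracked with at
#' most a window of lag.
#'
#' @param trace numeric pressure series, mmHg.
#' @param window_s rolling window, s.
#' @param sampling_rate Hz.
#' @param prob percentile used as baseline.
#' @return numeric baseline series, same length as `trace`.
#' @export
estimate_baseline <- function(trace, window_s = 60, sampling_rate = 10,
                              prob = 0.1) {
  n <- length(trace)
  if (all(is.na(trace))) stop("all-NA trace", call. = FALSE)
  fs <- sampling_rate
  hw <- round(window_s * fs / 2)
  anchors <- unique(c(seq(1L, n, by = max(1L, round(fs))), n))
  step <- max(1L, floor(fs / 2))
  q <- vapply(anchors, function(i) {
    idx <- seq(max(1L, i - hw), min(n, i + hw), by = step)
    stats::quantile(trace[idx], prob, na.rm = TRUE, names = FALSE)
  }, numeric(1))
  stats::approx(anchors, q, xout = seq_len(n), rule = 2)$y
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  stats::filter(x, rep(1 / k, k), sides = 2) |>
    as.numeric() |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

#' Detect per-sensor pressure transients
#'
#' Finds threshold crossings of (smoothed pressure - rolling baseline) at or
#' above `min_amplitude` on every functional colonic sensor, with onset and
#' offset placed where the excursion crosses 25% of its peak. Transients on
#' one sensor separated by less than `merge_gap_s` are merged; transients
#' whose onsets fall inside the artifact `mask` are dropped, as are
#' excursions narrower than `min_transient_duration_s` at the 25% level.
#' Sphincter channels (see [sphincter_channels()]) are excluded: they carry
#' tone and relaxations, not colonic contractions.
#'
#' @param rec an `hrcm_recording`.
#' @param thresholds a [classification_thresholds()] list.
#' @param mask optional logical vector (length = samples) of excluded time,
#'   from [exclusion_mask()].
#' @param detrended optional precomputed [detrended_matrix()]; computed on
#'   the fly when missing.
#' @return tibble with columns `sensor`, `onset_s`, `offset_s`, `peak_s`,
#'   `amplitude` (mmHg above baseline).
#' @export
detect_transients <- function(rec, thresholds = classification_thresholds(),
                              mask = NULL, detrended = NULL) {
  fs <- rec$sampling_rate
  th <- thresholds
  if (is.null(detrended)) detrended <- detrended_matrix(rec, th)
  use <- which(!is.na(detrended[, 1]))
  out <- lapply(use, function(s) {
    d <- detrended[s, ]
    iv <- transient_intervals(d, th$min_amplitude, th$merge_gap_s * fs)
    if (!nrow(iv)) return(NULL)
    keep <- (iv$end - iv$start) / fs >= th$min_transient_duration_s
    iv <- iv[keep, , drop = FALSE]
    if (!is.null(mask) && nrow(iv))
      iv <- iv[!mask[pmin(iv$start, length(mask))], , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    tibble::tibble(sensor = s,
                   onset_s = (iv$start - 1) / fs,
                   offset_s = (iv$end - 1) / fs,
                   peak_s = (iv$peak_at - 1) / fs,
                   amplitude = iv$peak)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out))
    out <- tibble::tibble(sensor = integer(), onset_s = double(),
                          offset_s = double(), peak_s = double(),
                          amplitude = double())
  dplyr::arrange(out, .data$onset_s, .data$sensor)
}

#' Baseline-subtracted pressure matrix
#'
#' Smooths every functional colonic sensor's trace with the moving-average
#' pre-smoother and subtracts the rolling-percentile baseline. Sphincter
#' channels and malfunctioning sensors get `NA` rows. Computed once per
#' recording and shared by the detection stages.
#'
#' @param rec an `hrcm_recording`.
#' @param thresholds a [classification_thresholds()] list.
#' @return numeric matrix, same shape as `rec$pressures`.
#' @export
detrended_matrix <- function(rec, thresholds = classification_thresholds()) {
  fs <- rec$sampling_rate
  k <- max(1L, round(thresholds$smooth_s * fs))
  use <- setdiff(which(rec$functional_mask), sphincter_channels(rec))
  d <- matrix(NA_real_, rec$n_sensors, ncol(rec$pressures))
  for (s in use) {
    x <- moving_average(rec$pressures[s, ], k)
    d[s, ] <- x - estimate_baseline(x, thresholds$baseline_window_s, fs)
  }
  d
}

# supra-threshold excursions of d, expanded to the 25%-of-peak crossings and
# merged when closer than gap_samples; returns data.frame of sample indices
transient_intervals <- function(d, min_amplitude, gap_samples,
                                rel_level = 0.25) {
  above <- !is.na(d) & d >= min_amplitude
  if (!any(above)) return(data.frame(start = integer(), end = integer(),
                                     peak = double(), peak_at = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  n <- length(d)
  reg <- matrix(0L, nrow(runs), 2)
  for (i in seq_len(nrow(runs))) {
    pk <- max(d[runs[i, 1]:runs[i, 2]])
    thr <- rel_level * pk
    i0 <- runs[i, 1]
    while (i0 > 1L && !is.na(d[i0 - 1L]) && d[i0 - 1L] >= thr) i0 <- i0 - 1L
    i1 <- runs[i, 2]
    while (i1 < n && !is.na(d[i1 + 1L]) && d[i1 + 1L] >= thr) i1 <- i1 + 1L
    reg[i, ] <- c(i0, i1)
  }
  # merge overlapping / nearby regions
  o <- order(reg[, 1])
  reg <- reg[o, , drop = FALSE]
  merged <- list(reg[1, ])
  for (i in seq_len(nrow(reg))[-1]) {
    last <- merged[[length(merged)]]
    if (reg[i, 1] - last[2] <= gap_samples) {
      merged[[length(merged)]] <- c(last[1], max(last[2], reg[i, 2]))
    } else merged[[length(merged) + 1L]] <- reg[i, ]
  }
  m <- do.call(rbind, merged)
  peak <- peak_at <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    seg <- d[m[i, 1]:m[i, 2]]
    peak[i] <- max(seg)
    peak_at[i] <- m[i, 1] + which.max(seg) - 1L
  }
  data.frame(start = m[, 1], end = m[, 2], peak = peak, peak_at = peak_at)
}

#' Group per-sensor transients into candidate multi-sensor events
#'
#' Chains transients on adjacent sensors into one candidate event when their
#' onsets lie within `onset_group_window_s` of each other, or when their
#' time intervals overlap by at least half the shorter interval (onset
#' jitter under noise can push two members of a genuinely simultaneous wave
#' just past the onset window, but their excursions still overlap almost
#' completely). The closure is transitive, so a wave marching across the
#' array at constant velocity forms a single candidate. Each transient
#' belongs to exactly one candidate; unchained transients become
#' single-sensor candidates.
#'
#' @param transients tibble from [detect_transients()].
#' @param thresholds a [classification_thresholds()] list.
#' @return the input tibble with an added integer `candidate` column.
#' @export
group_transients <- function(transients,
                             thresholds = classification_thresholds()) {
  n <- nrow(transients)
  if (!n) return(dplyr::mutate(transients, candidate = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  win <- thresholds$onset_group_window_s
  sensors <- sort(unique(transients$sensor))
  for (s in sensors) {
    a <- which(transients$sensor == s)
    b <- which(transients$sensor == s + 1L)
    if (!length(a) || !length(b)) next
    for (i in a) for (j in b) {
      ov <- min(transients$offset_s[i], transients$offset_s[j]) -
        max(transients$onset_s[i], transients$onset_s[j])
      shorter <- min(transients$offset_s[i] - transients$onset_s[i],
                     transients$offset_s[j] - transients$onset_s[j])
      if (abs(transients$onset_s[i] - transients$onset_s[j]) <= win ||
          ov >= 0.5 * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  transients$candidate <- match(roots, unique(roots))
  transients
}

#' Estimate propagation velocity of a candidate event
#'
#' Robust linear fit of earliest onset time against sensor position over the
#' member sensors: the slope magnitude comes from the Theil-Sen estimator
#' (median of pairwise slopes) and the flatness test from the least-squares
#' slope t-test. Velocity is signed: positive = antegrade (toward the anus,
#' decreasing sensor index). The front is reported as `simultaneous` when the
#' fitted |velocity| exceeds `simultaneity_velocity` (7 cm/s, the resolution
#' bound of a 1-cm array) or the onset-position trend is not distinguishable
#' from flat (p >= 0.05).
#'
#' @param candidate tibble of member transients (one candidate from
#'   [group_transients()]).
#' @param sensor_spacing cm between sensors.
#' @param thresholds a [classification_thresholds()] list.
#' @return list with `velocity` (signed cm/s, `NA` when simultaneous or
#'   undefined), `simultaneous` (logical), `undefined` (logical, `TRUE` when
#'   fewer than 3 member sensors).
#' @export
estimate_velocity <- function(candidate, sensor_spacing = 1,
                              thresholds = classification_thresholds()) {
  onset <- tapply(candidate$onset_s, candidate$sensor, min)
  sensors <- as.integer(names(onset))
  if (length(sensors) < 3)
    return(list(velocity = NA_real_, simultaneous = NA, undefined = TRUE))
  pos <- sensors * sensor_spacing
  t <- as.numeric(onset)
  # Theil-Sen slope of onset vs position
  pairs <- utils::combn(length(pos), 2)
  slopes <- (t[pairs[2, ]] - t[pairs[1, ]]) /
    (pos[pairs[2, ]] - pos[pairs[1, ]])
  slope <- stats::median(slopes)
  fit <- stats::lm(t ~ pos)
  p <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["pos", "Pr(>|t|)"]),
    error = function(e) NA_real_)
  if (is.na(p)) p <- 1  # zero-variance onsets: perfectly flat
  if (p >= 0.05 || slope == 0)
    return(list(velocity = NA_real_, simultaneous = TRUE, undefined = FALSE))
  v <- -1 / slope  # onset decreasing with position = toward anus = antegrade
  if (abs(v) > thresholds$simultaneity_velocity)
    return(list(velocity = NA_real_, simultaneous = TRUE, undefined = FALSE))
  list(velocity = v, simultaneous = FALSE, undefined = FALSE)
}
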