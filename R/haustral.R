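#' Per-sensor activity profile with rhythmicity testing
#'
#' For each sensor: the isolated-transient rate (per minute) in the analysis
#' window, and the dominant frequency of the transient train in the 1-6
#' cycles/min band with its spectral prominence. The train is binarized into
#' 1-s bins and its periodogram peak in the band is tested against the 95th
#' percentile of a shuffled-train null (shuffling destroys timing but keeps
#' the rate), so a Poisson train of the same rate is rejected at the ~5%
#' level. A dominant frequency is reported only when significant; windows
#' shorter than 5 min leave rhythmicity undetermined.
#'
#' @param transients tibble from [detect_transients()].
#' @param from_s,to_s analysis window, s.
#' @param n_sensors number of sensors to profile.
#' @param n_shuffle null-calibration shuffles.
#' @param null_seed RNG seed for the shuffled null (documented, fixed).
#' @return tibble with columns `sensor`, `rate_per_min`, `dominant_cpm`
#'   (`NA` when not significant or undetermined), `prominence` (peak power /
#'   null threshold).
#' @export
activity_profile <- function(transients, from_s, to_s, n_sensors = 36,
                             n_shuffle = 200, null_seed = 171) {
  dur_min <- (to_s - from_s) / 60
  tr <- dplyr::filter(transients, .data$onset_s >= from_s,
                      .data$onset_s < to_s)
  short <- (to_s - from_s) < 300
  out <- lapply(seq_len(n_sensors), function(s) {
    on <- tr$onset_s[tr$sensor == s]
    rate <- length(on) / dur_min
    if (short || length(on) < 4)
      return(tibble::tibble(sensor = s, rate_per_min = rate,
                            dominant_cpm = NA_real_, prominence = NA_real_))
    bins <- tabulate(floor(on - from_s) + 1L, nbins = ceiling(to_s - from_s))
    bins <- pmin(bins, 1L)
    sp <- train_periodogram(bins)
    band <- sp$freq_cpm >= 1 & sp$freq_cpm <= 6
    peak <- max(sp$power[band])
    peak_cpm <- sp$freq_cpm[band][which.max(sp$power[band])]
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(null_seed + s)
    null_max <- vapply(seq_len(n_shuffle), function(i) {
      spn <- train_periodogram(sample(bins))
      max(spn$power[band])
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    thr <- stats::quantile(null_max, 0.95, names = FALSE)
    sig <- peak > thr
    tibble::tibble(sensor = s, rate_per_min = rate,
                   dominant_cpm = if (sig) peak_cpm else NA_real_,
                   prominence = peak / thr)
  })
  dplyr::bind_rows(out)
}

# periodogram of a 1-Hz binary train; freq axis in cycles/min
train_periodogram <- function(bins) {
  n <- length(bins)
  x <- bins - mean(bins)
  p <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  list(freq_cpm = k / n * 60, power = p[k + 1L])
}

#' Detect haustral-boundary sensors
#'
#' Haustral boundaries appear as sensors carrying persistent isolated
#' pressure transients with little activity in between, typically spaced 3-5
#' cm (up to 8 cm) apart. Boundary sensors are local maxima of the
#' per-sensor transient rate whose rate is at least `rate_ratio` times the
#' mean rate of the intervening sensors; the set is accepted when at least
#' `min_boundaries` maxima show spacing coefficient of variation at most
#' `cv_max`.
#'
#' @param profile tibble from [activity_profile()].
#' @param rate_ratio boundary-to-intervening rate ratio.
#' @param min_boundaries minimum boundary count.
#' @param cv_max maximum spacing coefficient of variation.
#' @param sensor_spacing cm.
#' @return list of class `haustral_boundaries`: `sensors`,
#'   `mean_spacing_cm`, `spacing_cv`, `mean_frequency_cpm`. Empty `sensors`
#'   when no regular boundary set exists.
#' @export
detect_boundaries <- function(profile, rate_ratio = 3, min_boundaries = 3,
                              cv_max = 0.35, sensor_spacing = 1) {
  r <- profile$rate_per_min
  n <- length(r)
  loc_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) r[i - 1] else -Inf
    right <- if (i < n) r[i + 1] else -Inf
    r[i] > 0 & r[i] >= left & r[i] >= right
  }, logical(1)))
  empty <- structure(list(sensors = integer(), mean_spacing_cm = NA_real_,
                          spacing_cv = NA_real_,
                          mean_frequency_cpm = NA_real_),
                     class = "haustral_boundaries")
  if (length(loc_max) < min_boundaries) return(empty)
  # boundary test: rate dominates the intervening sensors
  keep <- vapply(seq_along(loc_max), function(k) {
    i <- loc_max[k]
    lo <- if (k > 1) loc_max[k - 1] else 0L
    hi <- if (k < length(loc_max)) loc_max[k + 1] else n + 1L
    between <- setdiff(seq(max(1L, lo + 1L), min(n, hi - 1L)), loc_max)
    m <- if (length(between)) mean(r[between]) else 0
    r[i] >= rate_ratio * m || m == 0
  }, logical(1))
  b <- loc_max[keep]
  if (length(b) < min_boundaries) return(empty)
  sp <- diff(b) * sensor_spacing
  cv <- stats::sd(sp) / mean(sp)
  if (is.na(cv) || cv > cv_max) return(empty)
  freq <- profile$dominant_cpm[match(b, profile$sensor)]
  structure(list(sensors = b, mean_spacing_cm = mean(sp), spacing_cv = cv,
                 mean_frequency_cpm = if (all(is.na(freq))) NA_real_ else
                   mean(freq, na.rm = TRUE)),
            class = "haustral_boundaries")
}

#' @export
print.haustral_boundaries <- function(x, ...) {
  if (!length(x$sensors)) {
    cat("<haustral_boundaries> none detected\n")
  } else {
    cat("<haustral_boundaries> sensors", paste(x$sensors, collapse = ", "),
        "| spacing", round(x$mean_spacing_cm, 2), "cm (cv",
        round(x$spacing_cv, 2), ")\n")
  }
  invisible(x)
}

#' Classify an intrahaustral window as segmentation / synchronized /
#' quiescent
#'
#' Over a window of 2-5 adjacent sensors and one time block: pressures are
#' averaged to 1 Hz and band-passed to 1-6 cycles/min; the mean pairwise
#' maximum cross-correlation over lags up to `max_lag_s` decides the state.
#' Coherent cycling across the window (mean r >= `r_threshold`) is
#' synchronized, with a velocity and direction derived from the pairwise
#' lags (|velocity| above 7 cm/s is reported as simultaneous within the
#' haustrum, direction `"simultaneous"`). Incoherent activity is
#' segmentation; a total transient rate under `quiescent_rate` per minute is
#' quiescent. The decision is invariant to per-sensor constant offsets and
#' to positive global amplitude scaling.
#'
#' @param rec an `hrcm_recording`.
#' @param sensor_window length-2 range of 2-5 adjacent sensors.
#' @param from_s,to_s time block (default block length 60 s resolves at
#'   least 3 cycles of a 3 cycles/min rhythm).
#' @param transients optional transient tibble (detected if missing).
#' @param r_threshold synchrony threshold on the mean pairwise correlation.
#' @param max_lag_s maximum cross-correlation lag, s.
#' @param quiescent_rate transient rate (per min) below which the window is
#'   quiescent.
#' @param thresholds detection thresholds (used when `transients` missing).
#' @return list: `state`, `r_bar`, `frequency_cpm`, `velocity`, `direction`.
#' @export
classify_window_state <- function(rec, sensor_window, from_s, to_s,
                                  transients = NULL, r_threshold = 0.6,
                                  max_lag_s = 10, quiescent_rate = 0.5,
                                  thresholds = classification_thresholds()) {
  sensors <- seq(sensor_window[1], sensor_window[2])
  if (length(sensors) < 2 || length(sensors) > 5)
    stop("sensor window must span 2-5 adjacent sensors", call. = FALSE)
  if (is.null(transients)) transients <- detect_transients(rec, thresholds)
  rate <- sum(transients$sensor %in% sensors &
                transients$onset_s >= from_s & transients$onset_s < to_s) /
    ((to_s - from_s) / 60)
  if (rate < quiescent_rate)
    return(list(state = "quiescent", r_bar = NA_real_,
                frequency_cpm = NA_real_, velocity = NA_real_,
                direction = NA_character_))
  fs <- rec$sampling_rate
  i0 <- max(1L, floor(from_s * fs) + 1L)
  i1 <- min(ncol(rec$pressures), ceiling(to_s * fs))
  seg <- rec$pressures[sensors, i0:i1, drop = FALSE]
  x1 <- t(apply(seg, 1, decimate_1hz, fs = fs))
  xf <- t(apply(x1, 1, bandpass_cpm))
  pairs <- utils::combn(length(sensors), 2)
  rr <- lag_at <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    cc <- best_xcorr(xf[pairs[1, p], ], xf[pairs[2, p], ], max_lag_s)
    rr[p] <- cc$r
    lag_at[p] <- cc$lag
  }
  r_bar <- mean(rr)
  freq <- dominant_cpm(colMeans(xf))
  if (r_bar < r_threshold)
    return(list(state = "segmentation", r_bar = r_bar, frequency_cpm = freq,
                velocity = NA_real_, direction = NA_character_))
  # lags relative to sensor order give the within-haustrum velocity
  # ccf(x_i, x_j) peaks at lag = delay_i - delay_j = (pos_j - pos_i) / v,
  # so the slope of lag against position difference is 1 / velocity
  dpos <- (sensors[pairs[2, ]] - sensors[pairs[1, ]]) * rec$sensor_spacing
  slope <- stats::median(lag_at / dpos)
  if (slope == 0 || abs(1 / slope) > 7) {
    vel <- NA_real_
    dir <- "simultaneous"
  } else {
    vel <- 1 / slope
    dir <- if (vel > 0) "antegrade" else "retrograde"
  }
  list(state = "synchronized", r_bar = r_bar, frequency_cpm = freq,
       velocity = vel, direction = dir)
}

episode_frequency <- function(rec, sensor_window, t0, t1) {
  fs <- rec$sampling_rate
  sensors <- seq(sensor_window[1], sensor_window[2])
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(ncol(rec$pressures), ceiling(t1 * fs))
  seg <- rec$pressures[sensors, i0:i1, drop = FALSE]
  x1 <- colMeans(t(apply(seg, 1, decimate_1hz, fs = fs)))
  dominant_cpm(bandpass_cpm(x1))
}

decimate_1hz <- function(x, fs) {
  n <- floor(length(x) / fs)
  colMeans(matrix(x[seq_len(n * fs)], nrow = fs))
}

bandpass_cpm <- function(x, low_cpm = 1, high_cpm = 6) {
  # 1-Hz series; band in Hz normalized by Nyquist 0.5
  w <- c(low_cpm, high_cpm) / 60 / 0.5
  bf <- signal::butter(2, w, type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

best_xcorr <- function(a, b, max_lag) {
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)
  i <- which.max(cc$acf)
  list(r = cc$acf[i], lag = cc$lag[i])
}

# dominant frequency of a 1-Hz series in the 1-8 cycles/min band;
# zero-padded so the peak of a single rhythm is located well below the
# 1/T bin spacing of a short block
dominant_cpm <- function(x, pad_factor = 8) {
  n <- length(x)
  if (n < 30) return(NA_real_)
  xp <- c(x - mean(x), rep(0, n * (pad_factor - 1)))
  p <- Mod(stats::fft(xp))^2
  np <- length(xp)
  k <- seq_len(floor(np / 2))
  f <- k / np * 60
  band <- f >= 1 & f <= 8
  if (!any(band)) return(NA_real_)
  f[band][which.max(p[k + 1L][band])]
}

#' Persistence of a haustral boundary set
#'
#' Haustral boundary patterns remain associated with the same sensors for
#' long stretches (tens of minutes to hours). Persistence is measured by
#' re-detecting boundaries in consecutive blocks and counting how long the
#' original set keeps re-appearing (each detected sensor within one sensor
#' of the original set).
#'
#' @param transients transient tibble from [detect_transients()].
#' @param boundaries a `haustral_boundaries` object (the reference set).
#' @param from_s,to_s analysis span, s.
#' @param block_s re-evaluation block length, s (default 30 min).
#' @param n_sensors sensor count.
#' @return persistence in seconds (length of the initial run of blocks
#'   reproducing the set).
#' @export
boundary_persistence <- function(transients, boundaries, from_s, to_s,
                                 block_s = 1800, n_sensors = 36) {
  if (!length(boundaries$sensors)) return(0)
  starts <- seq(from_s, to_s - block_s, by = block_s)
  persist <- 0
  for (t0 in starts) {
    pr <- activity_profile(transients, t0, t0 + block_s,
                           n_sensors = n_sensors)
    b <- detect_boundaries(pr)
    same <- length(b$sensors) == length(boundaries$sensors) &&
      all(abs(b$sensors - boundaries$sensors) <= 1)
    if (!same) break
    persist <- persist + block_s
  }
  persist
}

#' Full haustral analysis of a recording
#'
#' Runs the haustral stage end to end: per-sensor activity profile with
#' rhythmicity testing, boundary detection, state labeling of every
#' haustral window, and SHPW episode extraction. Haustral windows are the
#' sensor spans between adjacent detected boundaries (clipped to 2-5
#' sensors); when no boundary set is found, sliding 5-sensor windows are
#' used instead.
#'
#' @param rec an `hrcm_recording`.
#' @param transients optional transient tibble (detected if missing).
#' @param from_s,to_s analysis span, s.
#' @param block_s state-labeling block, s.
#' @param thresholds detection thresholds.
#' @return list: `profile`, `boundaries`, `windows` (list of sensor
#'   ranges), `states` (tibble with a `window` column), `episodes` (SHPW
#'   episode tibble with `window`), `switches`.
#' @export
analyze_haustral <- function(rec, transients = NULL, from_s = 0,
                             to_s = recording_duration(rec), block_s = 60,
                             thresholds = classification_thresholds()) {
  if (is.null(transients)) transients <- detect_transients(rec, thresholds)
  profile <- activity_profile(transients, from_s, to_s,
                              n_sensors = rec$n_sensors)
  boundaries <- detect_boundaries(profile,
                                  sensor_spacing = rec$sensor_spacing)
  windows <- if (length(boundaries$sensors) >= 2) {
    b <- boundaries$sensors
    lapply(seq_len(length(b) - 1), function(i) {
      lo <- b[i] + 1L
      hi <- min(b[i + 1] - 1L, lo + 4L)
      c(lo, max(hi, lo + 1L))
    })
  } else {
    starts <- seq(1L, rec$n_sensors - 4L, by = 5L)
    lapply(starts, function(s) c(s, s + 4L))
  }
  windows <- Filter(function(w) w[2] - w[1] >= 1 && w[2] <= rec$n_sensors,
                    windows)
  states <- list()
  episodes <- list()
  switches <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    st <- haustral_states(rec, w, from_s, to_s, block_s = block_s,
                          transients = transients)
    ep <- shpw_episodes(st, rec = rec, sensor_window = w)
    lab <- paste0(w[1], "-", w[2])
    states[[i]] <- dplyr::mutate(st, window = lab, .before = 1)
    if (nrow(ep$episodes))
      episodes[[i]] <- dplyr::mutate(ep$episodes, window = lab,
                                     .before = 1)
    switches[[lab]] <- ep$switches
  }
  list(profile = profile, boundaries = boundaries, windows = windows,
       states = dplyr::bind_rows(states),
       episodes = if (length(episodes)) dplyr::bind_rows(episodes) else
         tibble::tibble(window = character(), start_s = double(),
                        end_s = double(), duration_s = double(),
                        frequency_cpm = double(), direction = character()),
       switches = switches)
}

#' Label the intrahaustral state over time
#'
#' Tiles the analysis span into fixed blocks and classifies each with
#' [classify_window_state()].
#'
#' @inheritParams classify_window_state
#' @param block_s block length, s.
#' @return tibble: `start_s`, `end_s`, `state`, `r_bar`, `frequency_cpm`,
#'   `velocity`, `direction`.
#' @export
haustral_states <- function(rec, sensor_window, from_s = 0,
                            to_s = recording_duration(rec), block_s = 60,
                            transients = NULL,
                            thresholds = classification_thresholds(), ...) {
  if (is.null(transients)) transients <- detect_transients(rec, thresholds)
  starts <- seq(from_s, to_s - block_s, by = block_s)
  out <- lapply(starts, function(t0) {
    st <- classify_window_state(rec, sensor_window, t0, t0 + block_s,
                                transients = transients, ...)
    tibble::tibble(start_s = t0, end_s = t0 + block_s, state = st$state,
                   r_bar = st$r_bar, frequency_cpm = st$frequency_cpm,
                   velocity = st$velocity, direction = st$direction)
  })
  dplyr::bind_rows(out)
}

#' Extract synchronized-haustral-pressure-wave episodes
#'
#' Merges runs of synchronized blocks of at least `min_episode_s` into SHPW
#' episodes (these occur for 2-10 min, 1-3 times a session, or not at all),
#' with each episode's mean frequency and direction (antegrade or retrograde
#' when at least `direction_agreement` of blocks agree in sign, otherwise
#' mixed - the usual case), plus the segmentation/synchronized alternation
#' switch times.
#'
#' @param states tibble from [haustral_states()].
#' @param min_episode_s minimum episode duration, s.
#' @param direction_agreement fraction of velocity signs that must agree.
#' @param rec,sensor_window when supplied, each episode's frequency is
#'   re-estimated from the band-passed window-mean pressure over the whole
#'   episode (much finer frequency resolution than a single 60-s block);
#'   otherwise the mean of the block estimates is used.
#' @return list: `episodes` tibble (`start_s`, `end_s`, `duration_s`,
#'   `frequency_cpm`, `direction`), `switches` (times where
#'   segmentation and synchronized alternate), `n_episodes`.
#' @export
shpw_episodes <- function(states, min_episode_s = 120,
                          direction_agreement = 0.7, rec = NULL,
                          sensor_window = NULL) {
  r <- rle(states$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  eps <- list()
  for (i in which(r$values == "synchronized")) {
    t0 <- states$start_s[starts[i]]
    t1 <- states$end_s[ends[i]]
    if (t1 - t0 < min_episode_s) next
    blocks <- states[starts[i]:ends[i], ]
    sgn <- sign(blocks$velocity[!is.na(blocks$velocity)])
    dir <- if (length(sgn) && mean(sgn > 0) >= direction_agreement)
      "antegrade"
    else if (length(sgn) && mean(sgn < 0) >= direction_agreement)
      "retrograde"
    else "mixed"
    freq <- if (!is.null(rec) && !is.null(sensor_window))
      episode_frequency(rec, sensor_window, t0, t1)
    else mean(blocks$frequency_cpm, na.rm = TRUE)
    eps[[length(eps) + 1L]] <- tibble::tibble(
      start_s = t0, end_s = t1, duration_s = t1 - t0,
      frequency_cpm = freq, direction = dir)
  }
  episodes <- if (length(eps)) dplyr::bind_rows(eps) else
    tibble::tibble(start_s = double(), end_s = double(),
                   duration_s = double(), frequency_cpm = double(),
                   direction = character())
  # alternation report: switch times between segmentation and synchronized
  sw <- numeric()
  for (i in seq_len(length(r$values) - 1)) {
    a <- r$values[i]; b <- r$values[i + 1]
    if (setequal(c(a, b), c("segmentation", "synchronized")))
      sw <- c(sw, states$start_s[starts[i + 1]])
  }
  list(episodes = episodes, switches = sw, n_episodes = nrow(episodes))
}
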