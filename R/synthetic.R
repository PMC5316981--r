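#' Synthetic recording buffer
#'
#' A mutable-in-spirit, functionally-updated container for building a
#' ground-truthed synthetic HRCM recording. `inject_*` functions take a
#' buffer, add a motor pattern or artifact to the pressure matrix, append the
#' corresponding ground-truth row (and annotation, for artifacts), and return
#' the updated buffer, so scenarios compose with the pipe.
#'
#' @param duration_s recording length, s.
#' @param sampling_rate Hz.
#' @param n_sensors sensor count (36 for the standard probe).
#' @param baseline_tone constant baseline pressure added to every sensor,
#'   mmHg.
#' @param sphincter optional [sphincter_spec()]; when present, the two most
#'   distal channels are rendered as the internal anal sphincter (resting
#'   tone, relaxation preceding SPW arrival, pressurization during
#'   cough/body-shift artifacts) at finalization.
#' @return an object of class `synth_buffer`.
#' @seealso [generate_recording()] for the scenario-level driver.
#' @export
synth_buffer <- function(duration_s, sampling_rate = 10, n_sensors = 36,
                         baseline_tone = 0, sphincter = NULL) {
  stopifnot(duration_s > 0)
  n_samp <- round(duration_s * sampling_rate)
  structure(
    list(pressures = matrix(baseline_tone, n_sensors, n_samp),
         sampling_rate = sampling_rate,
         n_sensors = n_sensors,
         duration_s = duration_s,
         sphincter = sphincter,
         truth = list(),
         annotations = list()),
    class = "synth_buffer")
}

#' Internal anal sphincter specification for the generator
#'
#' @param resting_tone tonic sphincter pressure, mmHg.
#' @param relaxation_depth fraction of the tone lost during a relaxation
#'   (0-1].
#' @param relaxation_lead_s seconds the relaxation precedes SPW arrival.
#' @param artifact_pressurization mmHg added to the sphincter channels during
#'   cough/body-shift artifacts.
#' @return a list of class `sphincter_spec`.
#' @export
sphincter_spec <- function(resting_tone = 40, relaxation_depth = 0.6,
                           relaxation_lead_s = 2,
                           artifact_pressurization = 15) {
  stopifnot(relaxation_depth > 0, relaxation_depth <= 1,
            relaxation_lead_s >= 0)
  structure(list(resting_tone = resting_tone,
                 relaxation_depth = relaxation_depth,
                 relaxation_lead_s = relaxation_lead_s,
                 artifact_pressurization = artifact_pressurization),
            class = "sphincter_spec")
}

truth_row <- function(kind, onset_s, duration_s, first_sensor, last_sensor,
                      amplitude, velocity = NA_real_, frequency_cpm = NA_real_,
                      onset_offsets = list(NULL)) {
  tibble::tibble(kind = kind, onset_s = onset_s, duration_s = duration_s,
                 first_sensor = as.integer(first_sensor),
                 last_sensor = as.integer(last_sensor),
                 amplitude = amplitude, velocity = velocity,
                 frequency_cpm = frequency_cpm,
                 onset_offsets = onset_offsets)
}

append_truth <- function(buf, row) {
  buf$truth[[length(buf$truth) + 1L]] <- row
  buf
}

#' Inject a simultaneous pressure wave
#'
#' Adds one SPW: the [spw_waveform()] morphology placed at the same onset on
#' every sensor of `span_sensors` (onset spread zero; a true SPW front moving
#' faster than the velocity resolution of a 1-cm array is indistinguishable
#' from simultaneous).
#'
#' @param buf a [synth_buffer()].
#' @param onset_s onset time, s.
#' @param amplitude peak amplitude, mmHg.
#' @param rise_s,decay_s morphology parameters, s.
#' @param span_sensors length-2 integer range of sensors carrying the wave.
#' @param superimposed add transients on the decay limb?
#' @param amplitude_jitter per-sensor multiplicative amplitude spread
#'   (uniform in `1 +/- amplitude_jitter`).
#' @return the updated buffer.
#' @export
inject_spw <- function(buf, onset_s, amplitude = 20, rise_s = 8, decay_s = 12,
                       span_sensors = c(1L, buf$n_sensors),
                       superimposed = TRUE, amplitude_jitter = 0.15) {
  fs <- buf$sampling_rate
  sensors <- seq(span_sensors[1], span_sensors[2])
  at <- round(onset_s * fs) + 1L
  for (s in sensors) {
    a <- amplitude * stats::runif(1, 1 - amplitude_jitter,
                                  1 + amplitude_jitter)
    buf$pressures[s, ] <- add_at(buf$pressures[s, ],
                                 spw_waveform(a, rise_s, decay_s,
                                              superimposed, fs), at)
  }
  append_truth(buf, truth_row("SPW", onset_s, rise_s + decay_s,
                              span_sensors[1], span_sensors[2], amplitude,
                              onset_offsets = list(rep(0, length(sensors)))))
}

#' Inject a propagating pressure wave
#'
#' Adds a wave whose onset marches across `span_sensors` at `velocity` cm/s:
#' positive velocity is antegrade (toward the anus, decreasing sensor index),
#' negative is retrograde (toward the most proximal sensor). Sensor i's onset
#' is offset from `onset_s` by its distance from the wave's starting end
#' divided by |velocity|.
#'
#' @inheritParams inject_spw
#' @param velocity signed propagation velocity, cm/s; must be non-zero.
#' @param duration_s per-sensor pressure-wave duration, s.
#' @param sensor_spacing cm between sensors.
#' @param kind ground-truth class; by default `"HAPW"` when `amplitude` >= 100,
#'   otherwise `"APW"` (velocity > 0) or `"RPW"`.
#' @return the updated buffer.
#' @export
inject_propagating_wave <- function(buf, onset_s, velocity, amplitude = 30,
                                    span_sensors = c(10L, 24L),
                                    duration_s = 10, amplitude_jitter = 0.15,
                                    sensor_spacing = 1, kind = NULL) {
  if (velocity == 0) stop("velocity must be non-zero", call. = FALSE)
  if (span_sensors[1] < 1 || span_sensors[2] > buf$n_sensors)
    stop("span outside sensor array", call. = FALSE)
  fs <- buf$sampling_rate
  sensors <- seq(span_sensors[1], span_sensors[2])
  pos <- sensors * sensor_spacing
  start_pos <- if (velocity > 0) max(pos) else min(pos)
  offsets <- (start_pos - pos) / velocity   # >= 0 for both directions
  if (is.null(kind))
    kind <- if (amplitude >= 100) "HAPW" else if (velocity > 0) "APW" else "RPW"
  for (k in seq_along(sensors)) {
    a <- amplitude * stats::runif(1, 1 - amplitude_jitter,
                                  1 + amplitude_jitter)
    w <- transient_waveform(a, duration_s, fs)
    buf$pressures[sensors[k], ] <-
      add_at(buf$pressures[sensors[k], ], w,
             round((onset_s + offsets[k]) * fs) + 1L)
  }
  append_truth(buf, truth_row(kind, onset_s, duration_s, span_sensors[1],
                              span_sensors[2], amplitude, velocity,
                              onset_offsets = list(offsets)))
}

#' Inject an isolated pressure transient
#'
#' A short-lasting pressure increase confined to one sensor.
#'
#' @inheritParams inject_spw
#' @param sensor sensor index.
#' @param duration_s transient width, s.
#' @return the updated buffer.
#' @export
inject_isolated_transient <- function(buf, onset_s, sensor, amplitude = 30,
                                      duration_s = 4) {
  fs <- buf$sampling_rate
  buf$pressures[sensor, ] <-
    add_at(buf$pressures[sensor, ],
           transient_waveform(amplitude, duration_s, fs),
           round(onset_s * fs) + 1L)
  append_truth(buf, truth_row("isolated_transient", onset_s, duration_s,
                              sensor, sensor, amplitude))
}

#' Inject rhythmic haustral-boundary activity
#'
#' Places trains of isolated pressure transients at non-adjacent boundary
#' sensors (3-5 cm apart in the colon, up to 8 cm), rhythmic at
#' `frequency_cpm` cycles/min with coefficient-of-variation `jitter_cv`,
#' leaving the sensors in between untouched.
#'
#' @inheritParams inject_spw
#' @param boundary_sensors integer vector of boundary sensor indices; must be
#'   pairwise non-adjacent.
#' @param frequency_cpm transient rate, cycles/min; 0 injects nothing.
#' @param jitter_cv coefficient of variation of inter-transient intervals.
#' @param from_s,to_s time window carrying the rhythm.
#' @param transient_duration_s width of each transient, s.
#' @return the updated buffer.
#' @export
inject_haustral_rhythm <- function(buf, boundary_sensors, frequency_cpm = 3,
                                   amplitude = 15, jitter_cv = 0,
                                   from_s = 0, to_s = buf$duration_s,
                                   transient_duration_s = 4) {
  bs <- sort(as.integer(boundary_sensors))
  if (any(bs < 1 | bs > buf$n_sensors))
    stop("boundary sensors outside array", call. = FALSE)
  if (any(diff(bs) == 1L))
    stop("boundary sensors must be non-adjacent", call. = FALSE)
  if (frequency_cpm <= 0) return(buf)
  period <- 60 / frequency_cpm
  for (s in bs) {
    times <- rhythmic_times(from_s, to_s, period, jitter_cv)
    for (tt in times) {
      buf$pressures[s, ] <-
        add_at(buf$pressures[s, ],
               transient_waveform(amplitude, transient_duration_s,
                                  buf$sampling_rate),
               round(tt * buf$sampling_rate) + 1L)
      buf <- append_truth(buf, truth_row("haustral_boundary", tt,
                                         transient_duration_s, s, s,
                                         amplitude,
                                         frequency_cpm = frequency_cpm))
    }
  }
  buf
}

# event times on [from, to) with mean spacing `period` and cv jitter
rhythmic_times <- function(from_s, to_s, period, cv = 0) {
  times <- numeric()
  t <- from_s + stats::runif(1, 0, period)
  while (t < to_s) {
    times <- c(times, t)
    t <- t + period * max(0.2, stats::rnorm(1, 1, cv))
  }
  times
}

#' Inject intrahaustral activity (segmentation / synchronized episodes)
#'
#' Builds the intrahaustral cyclic motor pattern over a window of 2-5 adjacent
#' sensors: `synchronized` episodes carry coherent cycles at `frequency_cpm`
#' whose onsets march across the window at `velocity` cm/s (synchronized
#' haustral pressure waves); `segmentation` episodes carry per-sensor
#' transients with independent timing and amplitudes (erratic,
#' small-intestine-like segmentation); `quiescent` episodes are silent.
#' Episodes follow `schedule` back-to-back from `start_s`.
#'
#' @inheritParams inject_spw
#' @param sensor_window integer range (length 2) of 2-5 adjacent sensors.
#' @param schedule tibble/data frame with columns `state`
#'   (`"segmentation"`, `"synchronized"` or `"quiescent"`) and `duration_s`.
#' @param frequency_cpm cycle rate, cycles/min.
#' @param velocity signed cm/s for synchronized cycles; sign may be
#'   alternated across cycles by `mixed_direction`.
#' @param mixed_direction alternate cycle direction (mixed-direction waves)?
#' @param start_s schedule start time, s.
#' @param sensor_spacing cm.
#' @return the updated buffer.
#' @export
inject_intrahaustral <- function(buf, sensor_window, schedule,
                                 frequency_cpm = 3, velocity = 2,
                                 amplitude = 12, mixed_direction = FALSE,
                                 start_s = 0, sensor_spacing = 1) {
  sensors <- seq(sensor_window[1], sensor_window[2])
  if (length(sensors) < 2 || length(sensors) > 5)
    stop("sensor window must span 2-5 adjacent sensors", call. = FALSE)
  schedule <- tibble::as_tibble(schedule)
  fs <- buf$sampling_rate
  period <- 60 / frequency_cpm
  pos <- sensors * sensor_spacing
  t0 <- start_s
  cyc_dur <- min(period * 0.6, 8)
  for (i in seq_len(nrow(schedule))) {
    st <- schedule$state[i]
    t1 <- min(t0 + schedule$duration_s[i], buf$duration_s)
    if (st == "synchronized") {
      times <- rhythmic_times(t0, t1 - cyc_dur, period, 0.05)
      dir <- 1
      for (tt in times) {
        v <- velocity * dir
        start_pos <- if (v > 0) max(pos) else min(pos)
        offs <- (start_pos - pos) / v
        for (k in seq_along(sensors)) {
          a <- amplitude * stats::runif(1, 0.85, 1.15)
          buf$pressures[sensors[k], ] <-
            add_at(buf$pressures[sensors[k], ],
                   transient_waveform(a, cyc_dur, fs),
                   round((tt + offs[k]) * fs) + 1L)
        }
        if (mixed_direction) dir <- -dir
      }
    } else if (st == "segmentation") {
      for (s in sensors) {
        times <- rhythmic_times(t0, t1 - cyc_dur, period, 0.6)
        for (tt in times) {
          a <- amplitude * stats::runif(1, 0.4, 1.8)
          buf$pressures[s, ] <-
            add_at(buf$pressures[s, ], transient_waveform(a, cyc_dur, fs),
                   round(tt * fs) + 1L)
        }
      }
    }
    if (st != "quiescent")
      buf <- append_truth(
        buf, truth_row(paste0(st, "_episode"), t0, t1 - t0,
                       sensor_window[1], sensor_window[2], amplitude,
                       velocity = if (st == "synchronized") velocity else NA,
                       frequency_cpm = frequency_cpm))
    t0 <- t1
  }
  buf
}

#' Inject an abdominal-pressure artifact
#'
#' Adds the pressure signature of a non-colonic event and the matching
#' annotation:
#' * `cough` — a short (< 1.5 s) sharp pressure spike in every sensor with
#'   onset spread below one sample;
#' * `body_shift` — a broad low-amplitude elevation across all sensors for
#'   the movement duration plus sustained non-rhythmic offsets at one or two
#'   single sensors;
#' * `talk` — about 5 mmHg, brief, all sensors;
#' * `drink` — about 10 mmHg, brief, all sensors.
#'
#' When the buffer carries a sphincter spec, the sphincter channels are
#' pressurized (not relaxed) during `cough` and `body_shift` at
#' finalization.
#'
#' @inheritParams inject_spw
#' @param kind one of `"cough"`, `"body_shift"`, `"talk"`, `"drink"`.
#' @param time_s artifact time, s.
#' @param amplitude peak amplitude, mmHg; defaults per kind (cough 25,
#'   body_shift 4, talk 5, drink 10).
#' @return the updated buffer.
#' @export
inject_artifact <- function(buf, kind, time_s, amplitude = NULL) {
  kinds <- c(cough = 25, body_shift = 4, talk = 5, drink = 10)
  if (!kind %in% names(kinds)) stop("unknown artifact kind: ", kind,
                                    call. = FALSE)
  if (time_s < 0 || time_s > buf$duration_s)
    stop("artifact time outside recording", call. = FALSE)
  amplitude <- amplitude %||% unname(kinds[kind])
  fs <- buf$sampling_rate
  at <- round(time_s * fs) + 1L
  dur <- switch(kind, cough = 1.0, body_shift = 6, talk = 2, drink = 2)
  if (kind == "cough") {
    # sharp rise: peak in the first quarter of the spike
    n <- max(2L, round(dur * fs))
    t <- seq(0, 1, length.out = n)
    g <- stats::dgamma(t, shape = 2, rate = 8)
    w <- amplitude * g / max(g)
  } else {
    w <- transient_waveform(amplitude, dur, fs)
  }
  for (s in seq_len(buf$n_sensors))
    buf$pressures[s, ] <- add_at(buf$pressures[s, ], w, at)
  if (kind == "body_shift") {
    extra <- sample(seq_len(buf$n_sensors), 2)
    for (s in extra) {
      off <- rep(8, round(60 * fs))
      # taper edges to avoid step discontinuities
      e <- round(2 * fs)
      off[1:e] <- seq(0, 8, length.out = e)
      off[(length(off) - e + 1):length(off)] <- seq(8, 0, length.out = e)
      buf$pressures[s, ] <- add_at(buf$pressures[s, ], off, at)
    }
  }
  buf$annotations[[length(buf$annotations) + 1L]] <-
    tibble::tibble(time_s = time_s,
                   kind = if (kind == "body_shift") "body_shift" else kind,
                   note = "synthetic")
  append_truth(buf, truth_row(paste0("artifact_", kind), time_s, dur, 1L,
                              buf$n_sensors, amplitude))
}

#' Finalize a synthetic buffer into a recording
#'
#' Renders the sphincter channels (if a [sphincter_spec()] is present):
#' channels 1-2 are replaced by the resting tone, relaxations that begin
#' `relaxation_lead_s` before each SPW's arrival, and pressurizations during
#' cough/body-shift artifacts. Then adds i.i.d. Gaussian noise of standard
#' deviation `noise_sd` and assembles the [recording()], ground-truth tibble
#' and annotation log.
#'
#' @param buf a [synth_buffer()].
#' @param noise_sd additive Gaussian noise SD, mmHg.
#' @param phases phase-window tibble (see [phase_windows()]); a
#'   `sphincter_pullback` phase spanning the recording is added automatically
#'   when a sphincter spec is present.
#' @param subject_id,tip_position passed to [recording()].
#' @return list with elements `recording`, `truth` (tibble), `annotations`
#'   (tibble).
#' @export
finalize_recording <- function(buf, noise_sd = 1, phases = NULL,
                               subject_id = "synthetic",
                               tip_position = 85) {
  truth <- if (length(buf$truth)) dplyr::bind_rows(buf$truth) else
    truth_row(character(), double(), double(), integer(), integer(),
              double())[0, ]
  truth <- dplyr::arrange(truth, .data$onset_s)
  fs <- buf$sampling_rate
  n_samp <- ncol(buf$pressures)
  if (!is.null(buf$sphincter)) {
    sp <- buf$sphincter
    trace <- rep(sp$resting_tone, n_samp)
    tm <- (seq_len(n_samp) - 1) / fs
    for (i in which(truth$kind == "SPW")) {
      t0 <- truth$onset_s[i] - sp$relaxation_lead_s
      t1 <- truth$onset_s[i] + truth$duration_s[i]
      depth <- sp$relaxation_depth * sp$resting_tone
      # smooth-edged relaxation window
      dip <- depth * pmin(1, pmax(0, (tm - t0) / 2)) *
        pmin(1, pmax(0, (t1 - tm) / 2))
      trace <- trace - pmin(dip, depth)
    }
    for (i in which(truth$kind %in% c("artifact_cough",
                                      "artifact_body_shift"))) {
      w <- transient_waveform(sp$artifact_pressurization,
                              truth$duration_s[i], fs)
      trace <- add_at(trace, w, round(truth$onset_s[i] * fs) + 1L)
    }
    trace <- pmax(trace, 0)
    buf$pressures[1, ] <- trace
    buf$pressures[2, ] <- trace
    sp_phase <- phase_windows("sphincter_pullback", 0, buf$duration_s)
    phases <- if (is.null(phases)) sp_phase else
      dplyr::bind_rows(phases, sp_phase)
  }
  noisy <- buf$pressures +
    matrix(stats::rnorm(length(buf$pressures), 0, noise_sd),
           nrow(buf$pressures))
  ann <- if (length(buf$annotations)) {
    dplyr::arrange(dplyr::bind_rows(buf$annotations), .data$time_s)
  } else annotation_log()
  rec <- recording(noisy, sampling_rate = fs, tip_position = tip_position,
                   phases = phases, subject_id = subject_id,
                   group = "synthetic")
  list(recording = rec, truth = truth, annotations = ann)
}

#' Generate a full ground-truthed synthetic recording
#'
#' Scenario-level driver: seeds the RNG, lays out event times for each
#' pattern spec (respecting per-phase rate multipliers that emulate the
#' gastro-colonic response to a meal), injects every pattern and artifact,
#' renders the sphincter channels and noise, and returns the recording with
#' its ground truth and annotation log. Deterministic for a fixed seed.
#'
#' @param duration_s recording length, s.
#' @param seed integer RNG seed fixing the entire output.
#' @param noise_sd Gaussian noise SD, mmHg.
#' @param baseline_tone constant baseline, mmHg.
#' @param patterns list of pattern specs built by [spw_train_spec()],
#'   [propagating_wave_spec()], [isolated_transient_spec()],
#'   [haustral_boundary_spec()], [intrahaustral_spec()], [artifact_spec()].
#' @param sphincter optional [sphincter_spec()].
#' @param phases optional phase tibble; may carry a `rate_multiplier` column
#'   scaling pattern rates within each phase (default 1).
#' @param sampling_rate,n_sensors array geometry.
#' @param subject_id,tip_position recording metadata.
#' @return list with `recording`, `truth`, `annotations`.
#' @examples
#' out <- generate_recording(600, seed = 1,
#'   patterns = list(spw_train_spec(rate_per_min = 0.5)))
#' nrow(out$truth)
#' @export
generate_recording <- function(duration_s, seed = 1, noise_sd = 1,
                               baseline_tone = 0, patterns = list(),
                               sphincter = NULL, phases = NULL,
                               sampling_rate = 10, n_sensors = 36,
                               subject_id = "synthetic", tip_position = 85) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  buf <- synth_buffer(duration_s, sampling_rate, n_sensors, baseline_tone,
                      sphincter)
  mult_fn <- rate_multiplier_fn(phases)
  for (sp in patterns) buf <- inject_pattern(buf, sp, mult_fn)
  finalize_recording(buf, noise_sd = noise_sd, phases = phases,
                     subject_id = subject_id, tip_position = tip_position)
}

rate_multiplier_fn <- function(phases) {
  if (is.null(phases) || !nrow(phases) || !"rate_multiplier" %in% names(phases))
    return(function(t) 1)
  function(t) {
    hit <- phases$rate_multiplier[phases$start_s <= t & t < phases$end_s]
    if (length(hit)) hit[1] else 1
  }
}

# sequential event times with local rate scaled by mult_fn(t); cv controls
# rhythmicity (0 = perfectly periodic, >= 1 ~ Poisson-like)
scaled_times <- function(rate_per_min, duration_s, cv, mult_fn,
                         margin_s = 0) {
  if (rate_per_min <= 0) return(numeric())
  times <- numeric()
  t <- stats::runif(1, 0, 60 / rate_per_min)
  while (t < duration_s - margin_s) {
    times <- c(times, t)
    base <- 60 / (rate_per_min * max(mult_fn(t), 1e-6))
    t <- t + base * max(0.2, stats::rnorm(1, 1, cv))
  }
  times
}

#' Pattern specifications for the scenario generator
#'
#' Constructors describing the stochastic layout of each motor pattern in a
#' [generate_recording()] scenario. Defaults follow typical observed values:
#' SPWs rise ~20 mmHg over ~8 s and decay over ~12 s spanning up to 35 cm,
#' rhythmic in the 0.5-3 cycles/min range; antegrade waves travel 4.8-7.2
#' cm/s and retrograde waves 0.6-3.7 cm/s; high-amplitude waves exceed 100
#' mmHg over at least 3 sensors; isolated transients span 5-230 mmHg
#' (log-normal, a modeling choice); haustral boundaries sit 3-5 (up to 8)
#' sensors apart and beat at ~3 cycles/min.
#'
#' @param rate_per_min mean event rate per minute (before phase multipliers).
#' @param amplitude peak amplitude, mmHg.
#' @param rise_s,decay_s SPW morphology, s.
#' @param span_sensors sensor range carried by each event.
#' @param rhythm_cv coefficient of variation of inter-event intervals.
#' @param superimposed add transients to SPW decay limbs?
#' @return a classed list consumed by [generate_recording()].
#' @name pattern_specs
#' @export
spw_train_spec <- function(rate_per_min = 1, amplitude = 20, rise_s = 8,
                           decay_s = 12, span_sensors = NULL,
                           rhythm_cv = 0.25, superimposed = TRUE) {
  structure(as.list(environment()), class = c("spw_train_spec",
                                              "pattern_spec"))
}

#' @rdname pattern_specs
#' @param velocity signed cm/s (positive antegrade).
#' @param duration_s per-sensor wave duration, s.
#' @param times_s explicit onset times; overrides `rate_per_min` when given.
#' @export
propagating_wave_spec <- function(rate_per_min = 0.5, velocity = 5,
                                  amplitude = 30, span_sensors = c(10L, 24L),
                                  duration_s = 10, rhythm_cv = 0.5,
                                  times_s = NULL) {
  structure(as.list(environment()), class = c("propagating_wave_spec",
                                              "pattern_spec"))
}

#' @rdname pattern_specs
#' @param sensors sensors eligible to carry isolated transients (default all
#'   colonic sensors).
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude parameters.
#' @param amplitude_range truncation bounds, mmHg.
#' @export
isolated_transient_spec <- function(rate_per_min = 2, sensors = NULL,
                                    amplitude_meanlog = log(25),
                                    amplitude_sdlog = 0.7,
                                    amplitude_range = c(5, 230),
                                    duration_s = c(2, 6)) {
  structure(as.list(environment()), class = c("isolated_transient_spec",
                                              "pattern_spec"))
}

#' @rdname pattern_specs
#' @param boundary_sensors boundary sensor indices (non-adjacent; typical
#'   spacing 3-5 sensors, up to 8).
#' @param frequency_cpm rhythm frequency, cycles/min.
#' @param jitter_cv interval jitter.
#' @export
haustral_boundary_spec <- function(boundary_sensors, frequency_cpm = 3,
                                   amplitude = 15, jitter_cv = 0.1) {
  structure(as.list(environment()), class = c("haustral_boundary_spec",
                                              "pattern_spec"))
}

#' @rdname pattern_specs
#' @param sensor_window 2-5 adjacent sensors (length-2 range).
#' @param schedule tibble of `state`, `duration_s` episodes.
#' @param mixed_direction alternate synchronized-cycle direction?
#' @param start_s schedule start, s.
#' @export
intrahaustral_spec <- function(sensor_window, schedule, frequency_cpm = 3,
                               velocity = 2, amplitude = 12,
                               mixed_direction = FALSE, start_s = 0) {
  structure(as.list(environment()), class = c("intrahaustral_spec",
                                              "pattern_spec"))
}

#' @rdname pattern_specs
#' @param kind artifact subtype.
#' @export
artifact_spec <- function(kind = "cough", times_s, amplitude = NULL) {
  structure(as.list(environment()), class = c("artifact_spec",
                                              "pattern_spec"))
}

#' Standard mixed-pattern validation recording
#'
#' Generates a session emulating typical observed activity with every event
#' class present and ground truth attached: SPWs (~20 mmHg, 8 s rise / 12 s
#' decay, full-array), APWs at 4.8-6 cm/s, RPWs at 0.8-3.5 cm/s, occasional
#' HAPWs (> 100 mmHg over 10 sensors), and isolated pressure transients.
#' Events are laid out on a jittered time grid so that successive events do
#' not overlap: coincident overlapping waves are ambiguous even to a human
#' scorer, and this scenario is meant to measure detector quality, not
#' overlap resolution. Deterministic for a fixed seed.
#'
#' @param duration_s session length, s.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise SD, mmHg.
#' @param sphincter optional [sphincter_spec()].
#' @param mean_gap_s mean spacing between successive events, s.
#' @param weights event-class probabilities (SPW, APW, RPW, HAPW,
#'   isolated_transient).
#' @return list with `recording`, `truth`, `annotations`.
#' @export
benchmark_recording <- function(duration_s = 900, seed = 1, noise_sd = 1,
                                sphincter = NULL, mean_gap_s = 34,
                                weights = c(0.30, 0.17, 0.17, 0.06, 0.30)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  buf <- synth_buffer(duration_s, sphincter = sphincter)
  lo <- if (is.null(buf$sphincter)) 1L else 3L
  t <- stats::runif(1, 30, 50)
  kinds <- c("SPW", "APW", "RPW", "HAPW", "isolated_transient")
  while (t < duration_s - 45) {
    k <- sample(kinds, 1, prob = weights)
    buf <- switch(k,
      SPW = inject_spw(buf, t, amplitude = stats::runif(1, 15, 30),
                       span_sensors = c(lo, buf$n_sensors)),
      APW = inject_propagating_wave(buf, t,
                                    velocity = stats::runif(1, 4.8, 6.0),
                                    amplitude = stats::runif(1, 20, 50),
                                    span_sensors = lo + c(5L, 19L)),
      RPW = inject_propagating_wave(buf, t,
                                    velocity = -stats::runif(1, 0.8, 3.5),
                                    amplitude = stats::runif(1, 15, 40),
                                    span_sensors = lo + c(15L, 25L)),
      HAPW = inject_propagating_wave(buf, t,
                                     velocity = stats::runif(1, 0.8, 1.5),
                                     amplitude = stats::runif(1, 110, 140),
                                     span_sensors = lo + c(20L, 29L)),
      isolated_transient = inject_isolated_transient(
        buf, t, sample(seq(lo, buf$n_sensors), 1),
        amplitude = min(230, stats::rlnorm(1, log(30), 0.6) + 8),
        duration_s = stats::runif(1, 2.5, 6)))
    t <- t + stats::runif(1, mean_gap_s - 6, mean_gap_s + 6)
  }
  finalize_recording(buf, noise_sd = noise_sd)
}

inject_pattern <- function(buf, sp, mult_fn) UseMethod("inject_pattern", sp)

#' @export
inject_pattern.spw_train_spec <- function(buf, sp, mult_fn) {
  span <- sp$span_sensors %||%
    c(if (is.null(buf$sphincter)) 1L else 3L, buf$n_sensors)
  times <- scaled_times(sp$rate_per_min, buf$duration_s, sp$rhythm_cv,
                        mult_fn, margin_s = sp$rise_s + sp$decay_s)
  for (tt in times)
    buf <- inject_spw(buf, tt, sp$amplitude, sp$rise_s, sp$decay_s, span,
                      sp$superimposed)
  buf
}

#' @export
inject_pattern.propagating_wave_spec <- function(buf, sp, mult_fn) {
  travel <- abs(diff(sp$span_sensors)) / abs(sp$velocity)
  times <- sp$times_s %||%
    scaled_times(sp$rate_per_min, buf$duration_s, sp$rhythm_cv, mult_fn,
                 margin_s = sp$duration_s + travel)
  for (tt in times)
    buf <- inject_propagating_wave(buf, tt, sp$velocity, sp$amplitude,
                                   sp$span_sensors, sp$duration_s)
  buf
}

#' @export
inject_pattern.isolated_transient_spec <- function(buf, sp, mult_fn) {
  sensors <- sp$sensors %||%
    seq(if (is.null(buf$sphincter)) 1L else 3L, buf$n_sensors)
  times <- scaled_times(sp$rate_per_min, buf$duration_s, 1, mult_fn,
                        margin_s = max(sp$duration_s))
  for (tt in times) {
    a <- min(max(stats::rlnorm(1, sp$amplitude_meanlog, sp$amplitude_sdlog),
                 sp$amplitude_range[1]), sp$amplitude_range[2])
    buf <- inject_isolated_transient(
      buf, tt, sample(sensors, 1), a,
      stats::runif(1, sp$duration_s[1], sp$duration_s[2]))
  }
  buf
}

#' @export
inject_pattern.haustral_boundary_spec <- function(buf, sp, mult_fn) {
  inject_haustral_rhythm(buf, sp$boundary_sensors, sp$frequency_cpm,
                         sp$amplitude, sp$jitter_cv)
}

#' @export
inject_pattern.intrahaustral_spec <- function(buf, sp, mult_fn) {
  inject_intrahaustral(buf, sp$sensor_window, sp$schedule, sp$frequency_cpm,
                       sp$velocity, sp$amplitude, sp$mixed_direction,
                       sp$start_s)
}

#' @export
inject_pattern.artifact_spec <- function(buf, sp, mult_fn) {
  for (tt in sp$times_s)
    buf <- inject_artifact(buf, sp$kind, tt, sp$amplitude)
  buf
}
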