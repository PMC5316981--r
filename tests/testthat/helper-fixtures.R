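# small programmatic fixtures shared across test files

# noise-free recording with a single injected event, for oracle tests
single_event_recording <- function(inject, duration_s = 120, seed = 1,
                                   noise_sd = 0, sphincter = NULL) {
  withr::with_seed(seed, {
    buf <- synth_buffer(duration_s, sphincter = sphincter)
    buf <- inject(buf)
    finalize_recording(buf, noise_sd = noise_sd)
  })
}

# matrix-level probe recording: rectangular pulses placed by hand, used for
# black-box probing of the classification constants
probe_recording <- function(n_sensors = 36, duration_s = 120,
                            sampling_rate = 10) {
  recording(matrix(0, n_sensors, duration_s * sampling_rate),
            sampling_rate = sampling_rate)
}

add_rect_pulse <- function(rec, sensor, onset_s, duration_s, amplitude) {
  fs <- rec$sampling_rate
  i0 <- round(onset_s * fs) + 1L
  i1 <- min(ncol(rec$pressures), i0 + round(duration_s * fs) - 1L)
  rec$pressures[sensor, i0:i1] <- rec$pressures[sensor, i0:i1] + amplitude
  rec
}

# greedy one-to-one matching of detected events to ground truth by class
match_counts <- function(truth, events, classes, tol_s = 6) {
  out <- matrix(0L, length(classes), 3,
                dimnames = list(classes, c("tp", "n_truth", "n_detected")))
  for (k in classes) {
    tt <- truth[truth$kind == k, ]
    ee <- events[events$kind == k, ]
    used <- rep(FALSE, nrow(ee))
    tp <- 0L
    for (i in seq_len(nrow(tt))) {
      j <- which(!used & abs(ee$onset_s - tt$onset_s[i]) <= tol_s)
      if (length(j)) {
        used[j[1]] <- TRUE
        tp <- tp + 1L
      }
    }
    out[k, ] <- c(tp, nrow(tt), nrow(ee))
  }
  out
}
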