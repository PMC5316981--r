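#' Single-sensor simultaneous-pressure-wave waveform
#'
#' The canonical SPW morphology: a smooth monotone rise to `amplitude` over
#' `rise_s` seconds, followed by a slower irregular return to baseline over
#' `decay_s` (exponential, reaching < 5% of peak at `decay_s` after the peak),
#' optionally with 1-3 short pressure transients superimposed on the decay
#' limb. The peak equals `amplitude` exactly, at `t = rise_s`; superimposed
#' transients are confined to the lower part of the decay limb so they never
#' exceed the main peak.
#'
#' Uses the session RNG for the superimposed transients; seed the RNG for
#' reproducibility.
#'
#' @param amplitude peak pressure above baseline, mmHg (>= 0).
#' @param rise_s rise time, s.
#' @param decay_s decay time constant window, s; the trace falls below 5% of
#'   `amplitude` within `decay_s` of the peak.
#' @param with_superimposed add 1-3 short transients on the decay limb?
#' @param sampling_rate Hz.
#' @return numeric vector of pressures (mmHg above baseline).
#' @examples
#' w <- spw_waveform(20, 8, 12, with_superimposed = FALSE)
#' max(w) # exactly 20
#' @export
spw_waveform <- function(amplitude, rise_s = 8, decay_s = 12,
                         with_superimposed = TRUE, sampling_rate = 10) {
  if (rise_s < 0 || decay_s < 0) stop("durations must be non-negative",
                                      call. = FALSE)
  stopifnot(amplitude >= 0)
  fs <- sampling_rate
  t <- seq(0, rise_s + 1.5 * decay_s, by = 1 / fs)
  tau <- decay_s / 3  # exp(-3) < 5% at decay_s past the peak
  w <- ifelse(t <= rise_s,
              amplitude * (1 - cos(pi * pmin(t / max(rise_s, 1e-9), 1))) / 2,
              amplitude * exp(-(t - rise_s) / max(tau, 1e-9)))
  # force the exact peak (grid may miss t == rise_s)
  w[which.min(abs(t - rise_s))] <- amplitude
  if (with_superimposed && amplitude > 0 && decay_s > 2) {
    nb <- sample(1:3, 1)
    for (i in seq_len(nb)) {
      at <- rise_s + stats::runif(1, 0.35, 0.95) * decay_s
      amp <- stats::runif(1, 0.10, 0.30) * amplitude
      dur <- stats::runif(1, 1.5, 2.5)
      w <- add_at(w, transient_waveform(amp, dur, fs),
                  round(at * fs) + 1L)
    }
    w <- pmin(w, amplitude)
  }
  w
}

#' Single pressure-transient waveform
#'
#' A smooth unimodal pulse (`sin^2` window) of given peak amplitude and
#' duration, the building block for isolated pressure transients, haustral
#' boundary transients and intrahaustral cycles.
#'
#' @param amplitude peak, mmHg.
#' @param duration_s total width, s.
#' @param sampling_rate Hz.
#' @return numeric vector.
#' @export
transient_waveform <- function(amplitude, duration_s, sampling_rate = 10) {
  n <- max(2L, round(duration_s * sampling_rate))
  t <- seq(0, 1, length.out = n)
  amplitude * sin(pi * t)^2
}

# add `w` into `x` starting at index `at` (1-based), clipping at both ends
add_at <- function(x, w, at) {
  i0 <- max(1L, at)
  i1 <- min(length(x), at + length(w) - 1L)
  if (i0 > i1) return(x)
  x[i0:i1] <- x[i0:i1] + w[(i0 - at + 1L):(i1 - at + 1L)]
  x
}
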