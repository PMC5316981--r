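test_that("SPW waveform has exact peak, monotone rise and bounded decay", {
  w <- spw_waveform(20, rise_s = 8, decay_s = 12, with_superimposed = FALSE)
  fs <- 10
  expect_equal(max(w), 20)
  expect_equal(which.max(w), 8 * fs + 1)
  rise <- w[1:(8 * fs + 1)]
  expect_true(all(diff(rise) >= 0))
  expect_lt(w[(8 + 12) * fs + 1], 0.05 * 20)  # < 5% of peak at decay_s
  expect_true(all(is.finite(w)) && sum(w) / fs > 0)
  expect_equal(spw_waveform(0, 8, 12), rep(0, length(w)))
  expect_error(spw_waveform(20, -1, 12), "non-negative")
  # superimposed transients stay on the decay limb and below the peak
  withr::with_seed(7, {
    ws <- spw_waveform(20, 8, 12, with_superimposed = TRUE)
    expect_equal(max(ws), 20)
    expect_true(any(ws[(10 * fs):length(ws)] >
                      w[(10 * fs):length(w)] + 0.5))
  })
})

test_that("propagating injection produces the right onset staircase", {
  buf <- synth_buffer(120)
  buf <- inject_propagating_wave(buf, 20, velocity = 5, amplitude = 30,
                                 span_sensors = c(10, 19),
                                 amplitude_jitter = 0)
  offs <- buf$truth[[1]]$onset_offsets[[1]]
  expect_equal(offs, seq(1.8, 0, by = -0.2))  # 0.2 s per sensor, distal last
  buf2 <- synth_buffer(120)
  buf2 <- inject_propagating_wave(buf2, 20, velocity = -1,
                                  span_sensors = c(10, 19))
  offs2 <- buf2$truth[[1]]$onset_offsets[[1]]
  expect_equal(offs2, seq(0, 9, by = 1))  # retrograde: proximal last
  expect_error(inject_propagating_wave(buf, 20, velocity = 0),
               "non-zero")
  expect_error(inject_propagating_wave(buf, 20, velocity = 5,
                                       span_sensors = c(30, 40)),
               "span")
  # very fast wave: onsets indistinguishable at 10 Hz
  buf3 <- synth_buffer(120)
  buf3 <- inject_propagating_wave(buf3, 20, velocity = 1000,
                                  span_sensors = c(1, 36))
  expect_true(all(abs(buf3$truth[[1]]$onset_offsets[[1]]) < 0.1))
})

test_that("haustral rhythm hits the boundary sensors and nothing between", {
  withr::with_seed(2, {
    buf <- synth_buffer(600)
    buf <- inject_haustral_rhythm(buf, c(11, 19, 27, 35), frequency_cpm = 3,
                                  amplitude = 15, jitter_cv = 0)
    truth <- dplyr::bind_rows(buf$truth)
    per_sensor <- table(truth$first_sensor)
    expect_setequal(as.integer(names(per_sensor)), c(11, 19, 27, 35))
    # ~3 per min over 10 min
    expect_true(all(per_sensor >= 28 & per_sensor <= 32))
    # jitter 0: exactly periodic
    iv <- diff(truth$onset_s[truth$first_sensor == 11])
    expect_equal(iv, rep(20, length(iv)))
    # untouched sensors carry no pressure
    expect_equal(max(abs(buf$pressures[c(12:18, 20:26), ])), 0)
  })
  expect_equal(
    length(synth_buffer(60) |>
             inject_haustral_rhythm(c(5, 10), frequency_cpm = 0) |>
             _$truth), 0)
  expect_error(inject_haustral_rhythm(synth_buffer(60), c(5, 6)),
               "non-adjacent")
})

test_that("intrahaustral schedule is honored with correct synchrony lags", {
  withr::with_seed(3, {
    sch <- tibble::tibble(state = c("segmentation", "synchronized"),
                          duration_s = c(120, 600))
    buf <- synth_buffer(720)
    buf <- inject_intrahaustral(buf, c(20, 24), sch, frequency_cpm = 3,
                                velocity = 2)
    truth <- dplyr::bind_rows(buf$truth)
    expect_equal(truth$kind, c("segmentation_episode", "synchronized_episode"))
    expect_equal(truth$duration_s, c(120, 600))
    # synchronized cycles: lag between adjacent sensors = spacing / velocity
    seg <- buf$pressures[20:24, (130 * 10):(700 * 10)]
    lags <- vapply(1:4, function(i) {
      cc <- ccf(seg[i, ], seg[i + 1, ], lag.max = 20, plot = FALSE)
      cc$lag[which.max(cc$acf)] / 10
    }, numeric(1))
    expect_equal(mean(lags), 0.5, tolerance = 0.1)  # 1 cm at 2 cm/s
  })
  expect_error(inject_intrahaustral(synth_buffer(60), c(1, 8),
                                    tibble::tibble(state = "synchronized",
                                                   duration_s = 60)),
               "2-5 adjacent")
})

test_that("segmentation episodes have uncorrelated per-sensor event trains", {
  # oracle over event trains: binarized 1-s bins of independent trains
  withr::with_seed(9, {
    sch <- tibble::tibble(state = "segmentation", duration_s = 600)
    buf <- synth_buffer(600)
    buf <- inject_intrahaustral(buf, c(10, 14), sch, frequency_cpm = 3)
    seg <- buf$pressures[10:14, ]
    cors <- combn(5, 2, function(ij)
      max(ccf(seg[ij[1], ], seg[ij[2], ], lag.max = 50,
              plot = FALSE)$acf))
    expect_lt(mean(cors), 0.45)
  })
})

test_that("artifact injection matches the published signatures", {
  withr::with_seed(5, {
    buf <- synth_buffer(300)
    buf <- inject_artifact(buf, "cough", 100)
    # all-sensor spike, onset spread < 1 sample, duration < 1.5 s
    onsets <- apply(buf$pressures, 1, function(x) which(x > 1)[1])
    expect_lte(diff(range(onsets)), 1)
    widths <- apply(buf$pressures, 1, function(x) sum(x > 1) / 10)
    expect_true(all(widths < 1.5))
    buf <- inject_artifact(buf, "talk", 200)
    expect_equal(max(buf$pressures[5, (199 * 10):(203 * 10)]), 5,
                 tolerance = 0.01)
    buf <- inject_artifact(buf, "drink", 250)
    expect_equal(max(buf$pressures[5, (249 * 10):(253 * 10)]), 10,
                 tolerance = 0.01)
    ann <- dplyr::bind_rows(buf$annotations)
    expect_equal(ann$kind, c("cough", "talk", "drink"))
    expect_error(inject_artifact(buf, "sneeze", 10), "unknown artifact")
  })
})

test_that("sphincter channels pressurize during coughs and relax before SPWs", {
  out <- single_event_recording(function(b) {
    b <- inject_spw(b, 60, amplitude = 20, span_sensors = c(3, 36))
    inject_artifact(b, "cough", 150)
  }, duration_s = 300, seed = 6, noise_sd = 0,
  sphincter = sphincter_spec(resting_tone = 40, relaxation_depth = 0.6,
                             relaxation_lead_s = 2))
  tr <- out$recording$pressures[1, ]
  # relaxation starts before SPW onset and dips by depth * tone
  expect_lt(tr[60 * 10], 40 - 5)            # already below tone at onset
  expect_equal(min(tr[(58 * 10):(80 * 10)]), 40 * 0.4, tolerance = 1)
  # cough: tone + pressurization, no dip
  cough_win <- tr[(149 * 10):(152 * 10)]
  expect_gt(max(cough_win), 40 + 10)
  expect_gt(min(tr[(145 * 10):(155 * 10)]), 35)
})

test_that("generate_recording is deterministic and honors ground truth", {
  pats <- list(spw_train_spec(rate_per_min = 0.5),
               isolated_transient_spec(rate_per_min = 1))
  a <- generate_recording(300, seed = 42, patterns = pats)
  b <- generate_recording(300, seed = 42, patterns = pats)
  expect_identical(a$recording$pressures, b$recording$pressures)
  expect_identical(a$truth, b$truth)
  # empty spec list: noise only, no truth
  n <- generate_recording(300, seed = 1, patterns = list())
  expect_equal(nrow(n$truth), 0)
  expect_lt(max(abs(n$recording$pressures)), 6)
  # truth is sorted and one row per injected event
  expect_true(!is.unsorted(a$truth$onset_s))
})

test_that("truth amplitudes match the realized matrix at event centers", {
  out <- generate_recording(600, seed = 8, noise_sd = 1, patterns = list(
    propagating_wave_spec(rate_per_min = 0.5, velocity = 3, amplitude = 40,
                          span_sensors = c(10, 20))))
  fs <- out$recording$sampling_rate
  for (i in seq_len(nrow(out$truth))) {
    ev <- out$truth[i, ]
    s <- ev$first_sensor
    at <- round((ev$onset_s + ev$onset_offsets[[1]][1] +
                   ev$duration_s / 2) * fs) + 1L
    realized <- max(out$recording$pressures[s, at + (-5:5)])
    # per-sensor amplitude jitter is 15%; noise adds on top
    expect_lt(abs(realized - ev$amplitude), 0.15 * ev$amplitude + 3 * 1)
  }
})

test_that("postprandial rate multipliers raise pattern rates", {
  ph <- phase_windows(c("baseline", "postprandial"), c(0, 900), c(900, 1800))
  ph$rate_multiplier <- c(1, 3)
  out <- generate_recording(1800, seed = 10, patterns = list(
    spw_train_spec(rate_per_min = 0.4, rhythm_cv = 0.2)), phases = ph)
  n_base <- sum(out$truth$onset_s < 900)
  n_post <- sum(out$truth$onset_s >= 900)
  expect_gt(n_post, 2 * n_base)
})
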