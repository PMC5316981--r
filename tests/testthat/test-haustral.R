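test_that("activity profile finds true rhythms and rejects Poisson trains", {
  # exactly periodic 20-s train -> dominant 3 cycles/min
  tr <- tibble::tibble(sensor = 7L, onset_s = seq(10, 590, by = 20),
                       offset_s = seq(10, 590, by = 20) + 3,
                       peak_s = seq(10, 590, by = 20) + 1.5, amplitude = 15)
  pr <- activity_profile(tr, 0, 600, n_sensors = 10)
  expect_equal(pr$rate_per_min[7], 2.9, tolerance = 0.1)
  expect_equal(pr$dominant_cpm[7], 3, tolerance = 0.1)
  # empty sensors: rate 0, no rhythm
  expect_equal(pr$rate_per_min[1], 0)
  expect_true(is.na(pr$dominant_cpm[1]))
  # windows under 5 min leave rhythmicity undetermined
  pr_short <- activity_profile(tr, 0, 240, n_sensors = 10)
  expect_true(all(is.na(pr_short$dominant_cpm)))
  # null calibration: Poisson trains of the same rate are called rhythmic
  # in at most ~10% of draws
  hits <- 0L
  for (i in 1:40) {
    on <- withr::with_seed(1000 + i, sort(runif(30, 0, 600)))
    trp <- tibble::tibble(sensor = 1L, onset_s = on, offset_s = on + 3,
                          peak_s = on + 1.5, amplitude = 15)
    prp <- activity_profile(trp, 0, 600, n_sensors = 1)
    hits <- hits + !is.na(prp$dominant_cpm[1])
  }
  expect_lte(hits / 40, 0.10)
})

test_that("boundary detection recovers the printed 8-cm sensor set", {
  out <- generate_recording(1200, seed = 5, noise_sd = 1, patterns = list(
    haustral_boundary_spec(c(11, 19, 27, 35), frequency_cpm = 3,
                           amplitude = 15, jitter_cv = 0.1)))
  pr <- activity_profile(detect_transients(out$recording), 0, 1200)
  b <- detect_boundaries(pr)
  expect_equal(b$sensors, c(11L, 19L, 27L, 35L))
  expect_equal(b$mean_spacing_cm, 8)
  expect_equal(b$mean_frequency_cpm, 3, tolerance = 0.3)
})

test_that("boundary spacing is recovered for 3-5 sensor spacings under noise", {
  for (gap in c(3, 4, 5)) {
    sensors <- seq(6, 34, by = gap)
    hits <- 0
    for (seed in 1:5) {
      out <- generate_recording(900, seed = seed, noise_sd = 1,
        patterns = list(haustral_boundary_spec(sensors, frequency_cpm = 3,
                                               amplitude = 15,
                                               jitter_cv = 0.15)))
      pr <- activity_profile(detect_transients(out$recording), 0, 900)
      b <- detect_boundaries(pr)
      if (length(b$sensors) &&
          abs(b$mean_spacing_cm - gap) <= 1) hits <- hits + 1
    }
    expect_gte(hits, 4)
  }
  # uniform activity on all sensors: no boundary set
  out_u <- generate_recording(600, seed = 9, noise_sd = 1, patterns = list(
    isolated_transient_spec(rate_per_min = 10)))
  pr_u <- activity_profile(detect_transients(out_u$recording), 0, 600)
  expect_equal(length(detect_boundaries(pr_u)$sensors), 0)
})

test_that("window state separates synchronized, segmentation and quiescent", {
  # identical traces on 5 sensors: synchronized with zero lag
  rec <- probe_recording(duration_s = 300)
  wave <- 10 * sin(pi * 3 / 60 * (0:2999) / 10)^2  # 3 cycles/min
  for (s in 10:14) rec$pressures[s, ] <- wave
  rec$pressures <- rec$pressures + matrix(rnorm(36 * 3000, 0, 0.3), 36)
  st <- classify_window_state(rec, c(10, 14), 60, 180)
  expect_equal(st$state, "synchronized")
  expect_gt(st$r_bar, 0.9)
  expect_equal(st$direction, "simultaneous")
  expect_equal(st$frequency_cpm, 3, tolerance = 0.3)
  # flat traces: quiescent
  flat <- probe_recording(duration_s = 300)
  stq <- classify_window_state(flat, c(10, 14), 60, 180)
  expect_equal(stq$state, "quiescent")
  expect_error(classify_window_state(rec, c(1, 8), 0, 60), "2-5 adjacent")
})

test_that("independent per-sensor trains classify as segmentation", {
  # correlation-null oracle over generator segmentation episodes
  sch <- tibble::tibble(state = "segmentation", duration_s = 600)
  wrong <- 0L
  n_blocks <- 0L
  for (seed in 1:10) {
    out <- generate_recording(600, seed = seed, noise_sd = 1, patterns = list(
      intrahaustral_spec(c(20, 24), sch, frequency_cpm = 3)))
    st <- haustral_states(out$recording, c(20, 24), 0, 600)
    wrong <- wrong + sum(st$state == "synchronized")
    n_blocks <- n_blocks + nrow(st)
  }
  expect_lte(wrong / n_blocks, 0.10)
})

test_that("state decisions are invariant to offsets and positive scaling", {
  sch <- tibble::tibble(state = c("segmentation", "synchronized"),
                        duration_s = c(180, 240))
  out <- generate_recording(420, seed = 31, noise_sd = 1, patterns = list(
    intrahaustral_spec(c(20, 24), sch, frequency_cpm = 3, velocity = 2)))
  st0 <- haustral_states(out$recording, c(20, 24), 0, 420)
  rec_off <- out$recording
  rec_off$pressures <- rec_off$pressures + (10 + seq_len(36) %% 7)
  rec_scl <- out$recording
  rec_scl$pressures <- rec_scl$pressures * 3
  tr <- attr(detect_events(out$recording), "transients")
  expect_equal(haustral_states(rec_off, c(20, 24), 0, 420,
                               transients = tr)$state, st0$state)
  expect_equal(haustral_states(rec_scl, c(20, 24), 0, 420,
                               transients = tr)$state, st0$state)
})

test_that("synchronized frequency and alternation are recovered", {
  sch <- tibble::tibble(state = c("segmentation", "synchronized",
                                  "segmentation"),
                        duration_s = c(240, 300, 180))
  for (f in c(2, 3.5, 6)) {
    out <- generate_recording(720, seed = 11, noise_sd = 1, patterns = list(
      intrahaustral_spec(c(20, 24), sch, frequency_cpm = f, velocity = 2)))
    st <- haustral_states(out$recording, c(20, 24), 0, 720)
    ep <- shpw_episodes(st, rec = out$recording, sensor_window = c(20, 24))
    expect_equal(ep$n_episodes, 1)
    expect_equal(ep$episodes$frequency_cpm, f, tolerance = 0.3)
  }
})

test_that("episode extraction applies the minimum duration and direction
          rules", {
  mk_states <- function(states) tibble::tibble(
    start_s = 60 * (seq_along(states) - 1), end_s = 60 * seq_along(states),
    state = states, r_bar = 0.8, frequency_cpm = 3, velocity = 2,
    direction = "antegrade")
  # 4-min synchronized run: one episode of 240 s
  ep <- shpw_episodes(mk_states(c("segmentation", rep("synchronized", 4),
                                  "segmentation")))
  expect_equal(ep$n_episodes, 1)
  expect_equal(ep$episodes$duration_s, 240)
  expect_equal(length(ep$switches), 2)
  expect_equal(ep$episodes$direction, "antegrade")
  # alternating 60-s runs never reach the 120-s minimum
  ep2 <- shpw_episodes(mk_states(rep(c("synchronized", "segmentation"), 5)))
  expect_equal(ep2$n_episodes, 0)
  # mixed velocity signs -> mixed direction
  st3 <- mk_states(rep("synchronized", 4))
  st3$velocity <- c(2, -2, 2, -2)
  expect_equal(shpw_episodes(st3)$episodes$direction, "mixed")
})

test_that("end-to-end haustral analysis ties boundaries, states and
          episodes together", {
  sch <- tibble::tibble(state = c("segmentation", "synchronized"),
                        duration_s = c(240, 360))
  out <- generate_recording(600, seed = 47, noise_sd = 1, patterns = list(
    haustral_boundary_spec(c(8, 12, 16), frequency_cpm = 3, amplitude = 15,
                           jitter_cv = 0.1),
    intrahaustral_spec(c(25, 29), sch, frequency_cpm = 3, velocity = 2)))
  res <- analyze_haustral(out$recording)
  expect_s3_class(res$states, "tbl_df")
  expect_true(all(c("window", "state") %in% names(res$states)))
  # the intrahaustral window shows a synchronized episode somewhere
  expect_gte(nrow(res$episodes), 1)
  expect_true(any(res$episodes$start_s >= 200))
})

test_that("boundary persistence counts blocks reproducing the same set", {
  out <- generate_recording(5400, seed = 51, noise_sd = 1, patterns = list(
    haustral_boundary_spec(c(11, 19, 27, 35), frequency_cpm = 3,
                           amplitude = 15, jitter_cv = 0.1)))
  tr <- detect_transients(out$recording)
  pr <- activity_profile(tr, 0, 5400)
  b <- detect_boundaries(pr)
  expect_equal(boundary_persistence(tr, b, 0, 5400), 5400)
  # a set that never re-detects has zero persistence
  fake <- structure(list(sensors = c(2L, 6L, 10L)),
                    class = "haustral_boundaries")
  expect_equal(boundary_persistence(tr, fake, 0, 5400), 0)
})
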