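test_that("maximum sustained frequency follows the cv-window rule", {
  expect_equal(max_sustained_frequency(seq(0, 600, by = 60)), 1)
  expect_equal(max_sustained_frequency(seq(0, 300, by = 30)), 2)
  # invariant to events outside the rhythmic run
  on <- c(3, 42, seq(100, 220, by = 30), 391, 513)
  expect_equal(max_sustained_frequency(on), 2)
  expect_true(is.na(max_sustained_frequency(c(0, 10, 15))))
  # cv-window oracle: irregular Poisson onsets are mostly undefined
  undef <- 0L
  for (i in 1:20) {
    on <- withr::with_seed(300 + i, sort(runif(12, 0, 600)))
    undef <- undef + is.na(max_sustained_frequency(on))
  }
  expect_gte(undef / 20, 0.5)
})

test_that("session summaries convert counts to occurrence per 30 min", {
  rec <- recording(matrix(0, 36, 36000),
                   phases = phase_windows("baseline", 0, 3600))
  ev <- tibble::tibble(
    kind = "SPW", onset_s = seq(100, 3400, length.out = 10),
    offset_s = seq(100, 3400, length.out = 10) + 15, duration_s = 15,
    span_cm = 35, velocity = NA_real_, simultaneous = TRUE,
    amplitude_mean = 14, amplitude_max = 20, first_sensor = 1L,
    last_sensor = 36L, n_sensors = 36L,
    peak_s = seq(100, 3400, length.out = 10) + 7)
  s <- summarize_session(ev, rec)
  expect_equal(s$spw_per30, 5)  # 10 SPWs in 60 unmasked min
  expect_equal(s$spw_duration_s, 15)
  expect_equal(s$spw_distance_cm, 35)
  expect_equal(s$hapw_present, FALSE)
  # no events at all
  s0 <- summarize_session(ev[0, ], rec)
  expect_equal(s0$spw_per30, 0)
  expect_false(s0$shpw_present)
})

test_that("isolated transient metrics count sensors, time and categories", {
  # 18 sensors involved of 36 -> 50%
  iso <- tibble::tibble(first_sensor = rep(1:18, each = 2),
                        onset_s = rep(seq(10, 180, by = 10), 2),
                        duration_s = 3, amplitude_max = 30)
  m <- isolated_transient_metrics(iso, analyzed_s = 1800)
  expect_equal(m$it_pct_sensors, 50)
  # % time oracle: each of 36 functional sensors carries 6 s of the 1800 s
  # on 18 sensors -> mean over 36 sensors of (6/1800, or 0) = 0.167%
  expect_equal(m$it_pct_time, mean(c(rep(6 / 1800, 18), rep(0, 18))) * 100)
  # a sensor with 40- and 120-mmHg transients counts in both < 50 and > 100
  iso2 <- tibble::tibble(first_sensor = c(5L, 5L), onset_s = c(10, 60),
                         duration_s = 3, amplitude_max = c(40, 120))
  m2 <- isolated_transient_metrics(iso2, analyzed_s = 600)
  expect_equal(m2$it_pct_lt50, 100)
  expect_equal(m2$it_pct_gt100, 100)
  expect_equal(m2$it_pct_50_100, 0)
  expect_equal(m2$it_max_amplitude, 120)
})

test_that("paired t matches the textbook formula and suppresses small n", {
  x <- c(5, 7, 9, 4, 8, 6)
  y <- c(6, 9, 8, 7, 10, 7)
  cmp <- paired_compare(x, y, "toy")
  # textbook oracle
  d <- y - x
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(cmp$statistic, t_oracle)
  expect_equal(cmp$df, 5)
  expect_equal(cmp$p, p_oracle)
  # identical vectors: t = 0, p = 1
  cmp0 <- paired_compare(x, x)
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p, 1)
  # n < 5: suppressed, no p
  cmp3 <- paired_compare(c(1, 2, 3), c(2, 3, 4))
  expect_true(cmp3$suppressed)
  expect_true(is.na(cmp3$p))
  expect_error(paired_compare(1:3, 1:4), "length")
  td <- tidy(cmp)
  expect_equal(td$p.value, p_oracle)
  expect_s3_class(td, "tbl_df")
})

test_that("paired t keeps its nominal type-I error on null cohorts", {
  rej <- 0L
  for (i in 1:400) {
    withr::with_seed(5000 + i, {
      x <- rnorm(10)
      y <- x + rnorm(10)
    })
    if (paired_compare(x, y)$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 400, 0.07)
})

test_that("exact McNemar matches the binomial enumeration oracle", {
  # enumeration oracle: two-sided exact binomial over discordant pairs
  mcnemar_oracle <- function(b, c) {
    n <- b + c
    if (n == 0) return(1)
    pm <- dbinom(0:n, n, 0.5)
    min(1, sum(pm[pm <= pm[min(b, c) + 1] + 1e-12]))
  }
  for (b in 0:8) for (c in 0:8) {
    if (b + c == 0) next
    x <- rep(c(TRUE, FALSE, TRUE, FALSE), c(b, c, 3, 3))
    y <- rep(c(FALSE, TRUE, TRUE, FALSE), c(b, c, 3, 3))
    expect_equal(presence_compare(x, y, "within")$p, mcnemar_oracle(b, c),
                 info = paste(b, c))
  }
  # published example: 8 discordant pairs all one way -> p = 2 * 0.5^8
  x <- rep(c(FALSE, TRUE), c(8, 7))
  y <- rep(TRUE, 15)
  expect_equal(presence_compare(x, y, "within")$p, 2 * 0.5^8)
  # no discordant pairs -> p = 1
  expect_equal(presence_compare(y, y, "within")$p, 1)
})

test_that("Fisher exact matches the hypergeometric enumeration oracle", {
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b
    # enumerate all tables with the observed margins
    ks <- max(0, m - (b + d)):min(m, a + c)
    pk <- dhyper(ks, a + c, b + d, m)
    obs <- dhyper(a, a + c, b + d, m)
    sum(pk[pk <= obs * (1 + 1e-7)])
  }
  for (a in 0:6) for (b in 0:(6 - a)) for (c in 0:6) for (d in 0:(6 - c)) {
    if (a + b < 5 || c + d < 5) next
    x <- rep(c(TRUE, FALSE), c(a, b))
    y <- rep(c(TRUE, FALSE), c(c, d))
    expect_equal(presence_compare(x, y, "between")$p,
                 fisher_oracle(a, b, c, d), tolerance = 1e-10,
                 info = paste(a, b, c, d))
  }
  # (0,5; 5,0): the most extreme 5+5 table
  x <- rep(FALSE, 5)
  y <- rep(TRUE, 5)
  expect_equal(presence_compare(x, y, "between")$p,
               fisher_oracle(0, 5, 5, 0))
})

test_that("baseline-adjusted models recover group effects and flag
          separation", {
  # identical groups: coefficient ~ 0, p far from significant
  withr::with_seed(77, {
    base <- rnorm(60, 10, 2)
    post <- base + rnorm(60)
    grp <- rep(c("a", "b"), 30)
  })
  cmp <- baseline_adjusted_compare(post, base, grp)
  expect_lt(abs(cmp$estimate), 1)
  expect_gt(cmp$p, 0.1)
  # recovery oracle: known shift at n = 200, within 2 SE in >= 90% of runs
  hit <- 0L
  for (i in 1:100) {
    withr::with_seed(8000 + i, {
      base <- rnorm(200, 10, 2)
      grp <- rep(c("a", "b"), 100)
      post <- base + 1.5 * (grp == "b") + rnorm(200)
    })
    cc <- baseline_adjusted_compare(post, base, grp)
    se <- (cc$conf_high - cc$conf_low) / (2 * qt(0.975, cc$df))
    if (abs(cc$estimate - 1.5) <= 2 * se) hit <- hit + 1L
  }
  expect_gte(hit / 100, 0.9)
  # logistic with complete separation: flagged, p suppressed
  grp <- rep(c("a", "b"), 20)
  post_bin <- grp == "b"
  base <- rnorm(40)
  cs <- baseline_adjusted_compare(post_bin, base, grp, binary = TRUE)
  expect_true(cs$suppressed)
  expect_true(is.na(cs$p))
  # well-mixed logistic fits cleanly
  withr::with_seed(99, {
    base <- rnorm(120)
    grp <- rep(c("a", "b"), 60)
    post_bin <- runif(120) < plogis(0.5 * (grp == "b") + 0.3 * base)
  })
  cl <- baseline_adjusted_compare(post_bin, base, grp, binary = TRUE)
  expect_false(cl$suppressed)
  expect_true(cl$p >= 0 && cl$p <= 1)
})

test_that("cohort export formats cells as mean +/- SD (n)", {
  summaries <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 2),
    group = "constipation",
    phase = rep(c("baseline", "postprandial"), 2),
    spw_per30 = c(10, 16, 14, 20),
    hapw_present = c(FALSE, TRUE, FALSE, TRUE))
  tab <- export_table(summaries)
  expect_equal(nrow(tab), 2)
  cell <- tab$constipation_baseline[tab$metric == "spw_per30"]
  expect_match(cell, "12.0 ± 2.8 \\(2\\)")
  pres <- tab$constipation_postprandial[tab$metric == "hapw_present"]
  expect_match(pres, "2 \\(100.0%\\) \\(2\\)")
  dir <- withr::local_tempdir()
  export_table(summaries, file.path(dir, "table.tsv"))
  expect_true(file.exists(file.path(dir, "table.tsv")))
  # empty cohort: header-only table
  expect_equal(nrow(export_table(summaries[0, ])), 0)
})

test_that("a simulated cohort summary recovers distinct phase rates", {
  # two-phase sessions with tripled postprandial SPW rate
  per30 <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    ph <- phase_windows(c("baseline", "postprandial"), c(0, 900),
                        c(900, 1800))
    ph$rate_multiplier <- c(1, 3)
    out <- generate_recording(1800, seed = 40 + i, noise_sd = 1,
                              patterns = list(
                                spw_train_spec(rate_per_min = 0.33,
                                               rhythm_cv = 0.4)),
                              phases = ph)
    rec <- out$recording
    ev <- detect_events(rec, out$annotations)
    s <- summarize_session(ev, rec)
    per30[i, ] <- s$spw_per30
  }
  expect_equal(mean(per30[, 1]), 10, tolerance = 3)
  expect_gt(mean(per30[, 2]), 2 * mean(per30[, 1]))
})

test_that("the active-bins variant of percent time counts 1-min bins", {
  iso <- tibble::tibble(first_sensor = 4L, onset_s = c(10, 30, 130),
                        duration_s = 3, amplitude_max = 20)
  m <- isolated_transient_metrics(iso, analyzed_s = 600,
                                  functional_sensors = 1:4,
                                  time_method = "active_bins")
  # sensor 4 active in 2 of 10 bins; sensors 1-3 in none
  expect_equal(m$it_pct_time, mean(c(0, 0, 0, 0.2)) * 100)
})
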