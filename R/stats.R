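#' Maximum sustained frequency of an event train
#'
#' Irregular activity often alternates with periods of sustained
#' rhythmicity; the maximum frequency is the frequency within such a period,
#' an indication of the underlying pacemaker frequency. A sustained run is
#' at least `min_run` consecutive inter-onset intervals with coefficient of
#' variation at most `cv_max`; the reported value is 60 / mean interval of
#' the qualifying run with the highest frequency. Events outside the
#' rhythmic run do not affect the result.
#'
#' @param onsets event onset times, s.
#' @param cv_max maximum interval coefficient of variation.
#' @param min_run minimum number of consecutive intervals.
#' @return frequency in cycles/min, or `NA` when no run qualifies.
#' @export
max_sustained_frequency <- function(onsets, cv_max = 0.25, min_run = 3) {
  iv <- diff(sort(onsets))
  n <- length(iv)
  if (n < min_run) return(NA_real_)
  best <- NA_real_
  for (len in min_run:n) {
    for (i in seq_len(n - len + 1L)) {
      w <- iv[i:(i + len - 1L)]
      cv <- stats::sd(w) / mean(w)
      if (!is.na(cv) && cv <= cv_max) {
        f <- 60 / mean(w)
        if (is.na(best) || f > best) best <- f
      }
    }
  }
  best
}

#' Isolated-pressure-transient metrics for one phase
#'
#' The per-phase transient block: maximum amplitude; percentage of sensors
#' involved (denominator fixed at `n_sensors` = 36, the full probe, by
#' convention); mean percentage of time involved (summed transient durations
#' over unmasked phase time, averaged over functional sensors); and, over
#' the sensors showing any activity, the percentage whose transients reach
#' < 50, 50-100 and > 100 mmHg. A sensor recording pressures in more than
#' one category counts in each, so the three percentages may sum to more
#' than 100.
#'
#' @param iso tibble of isolated-transient events (columns `first_sensor`,
#'   `onset_s`, `duration_s`, `amplitude_max`).
#' @param analyzed_s unmasked phase duration, s.
#' @param n_sensors percentage denominator (36 by convention).
#' @param functional_sensors indices of functional colonic sensors (for the
#'   time-involved average).
#' @param time_method `"duration"` (summed transient durations over phase
#'   time, the default) or `"active_bins"` (fraction of 1-min bins with any
#'   activity) for the percentage of time involved.
#' @return one-row tibble: `it_max_amplitude`, `it_pct_sensors`,
#'   `it_pct_time`, `it_pct_lt50`, `it_pct_50_100`, `it_pct_gt100`.
#' @export
isolated_transient_metrics <- function(iso, analyzed_s, n_sensors = 36,
                                       functional_sensors = seq_len(36),
                                       time_method = c("duration",
                                                       "active_bins")) {
  time_method <- match.arg(time_method)
  if (!nrow(iso))
    return(tibble::tibble(it_max_amplitude = NA_real_, it_pct_sensors = 0,
                          it_pct_time = 0, it_pct_lt50 = NA_real_,
                          it_pct_50_100 = NA_real_, it_pct_gt100 = NA_real_))
  active <- unique(iso$first_sensor)
  per_sensor_time <- if (time_method == "duration") {
    vapply(functional_sensors, function(s)
      sum(iso$duration_s[iso$first_sensor == s]), numeric(1))
  } else {
    n_bins <- max(1, ceiling(analyzed_s / 60))
    vapply(functional_sensors, function(s) {
      on <- iso$onset_s[iso$first_sensor == s]
      length(unique(floor(on / 60))) / n_bins * analyzed_s
    }, numeric(1))
  }
  amp_by_sensor <- split(iso$amplitude_max, iso$first_sensor)
  in_cat <- function(lo, hi) mean(vapply(amp_by_sensor, function(a)
    any(a >= lo & a < hi), logical(1))) * 100
  tibble::tibble(
    it_max_amplitude = max(iso$amplitude_max),
    it_pct_sensors = length(active) / n_sensors * 100,
    it_pct_time = mean(per_sensor_time / analyzed_s) * 100,
    it_pct_lt50 = in_cat(-Inf, 50),
    it_pct_50_100 = in_cat(50, 100),
    it_pct_gt100 = in_cat(100, Inf))
}

#' Summarize one recording session per phase
#'
#' The per-subject, per-phase metric set: for each of SPW, APW and RPW the
#' occurrence per 30 min of unmasked time, the maximum sustained frequency,
#' and mean duration, propagation distance and amplitude; the
#' isolated-transient block; and HAPW / SHPW presence flags. Artifact-masked
#' time is removed from every per-time denominator.
#'
#' @param events event tibble from [detect_events()].
#' @param rec an `hrcm_recording`; its `phases` define the summary rows
#'   (phases other than `sphincter_pullback`; the whole recording when no
#'   phases are set).
#' @param episodes optional SHPW episode tibble (from [shpw_episodes()]).
#' @param mask optional exclusion mask (defaults to the mask attached to
#'   `events`).
#' @return tibble, one row per phase.
#' @export
summarize_session <- function(events, rec, episodes = NULL, mask = NULL) {
  if (is.null(mask)) mask <- attr(events, "mask")
  ph <- rec$phases[rec$phases$label != "sphincter_pullback", , drop = FALSE]
  if (!nrow(ph)) ph <- phase_windows("baseline", 0, recording_duration(rec))
  func <- setdiff(which(rec$functional_mask), sphincter_channels(rec))
  out <- lapply(seq_len(nrow(ph)), function(i) {
    t0 <- ph$start_s[i]; t1 <- ph$end_s[i]
    analyzed <- unmasked_seconds(mask, rec$sampling_rate, t0, t1)
    ev <- events[events$onset_s >= t0 & events$onset_s < t1, , drop = FALSE]
    class_block <- function(kind) {
      e <- ev[ev$kind == kind, , drop = FALSE]
      tibble::tibble(
        per30 = if (analyzed > 0) nrow(e) * 1800 / analyzed else NA_real_,
        maxfreq_cpm = max_sustained_frequency(e$onset_s),
        duration_s = if (nrow(e)) mean(e$duration_s) else NA_real_,
        distance_cm = if (nrow(e)) mean(e$span_cm) else NA_real_,
        amplitude = if (nrow(e)) mean(e$amplitude_mean) else NA_real_) |>
        stats::setNames(paste0(tolower(kind), "_",
                               c("per30", "maxfreq_cpm", "duration_s",
                                 "distance_cm", "amplitude")))
    }
    iso <- ev[ev$kind == "isolated_transient", , drop = FALSE]
    shpw <- !is.null(episodes) && nrow(episodes) &&
      any(episodes$start_s < t1 & episodes$end_s > t0)
    dplyr::bind_cols(
      tibble::tibble(phase = ph$label[i], analyzed_s = analyzed),
      class_block("SPW"), class_block("APW"), class_block("RPW"),
      isolated_transient_metrics(iso, analyzed, functional_sensors = func),
      tibble::tibble(hapw_present = any(ev$kind == "HAPW"),
                     shpw_present = shpw))
  })
  dplyr::bind_rows(out)
}

new_comparison <- function(metric, method, estimate = NA_real_,
                           statistic = NA_real_, df = NA_real_,
                           p = NA_real_, n = NA_integer_,
                           conf_low = NA_real_, conf_high = NA_real_,
                           suppressed = FALSE, note = "") {
  structure(list(metric = metric, method = method, estimate = estimate,
                 statistic = statistic, df = df, p = p, n = n,
                 conf_low = conf_low, conf_high = conf_high,
                 suppressed = suppressed, note = note),
            class = "motor_comparison")
}

#' @export
print.motor_comparison <- function(x, ...) {
  cat("<motor_comparison> ", x$metric, " [", x$method, "]\n", sep = "")
  if (x$suppressed) {
    cat("  suppressed (", x$note, "), n = ", x$n, "\n", sep = "")
  } else {
    cat("  estimate ", signif(x$estimate, 4), ", statistic ",
        signif(x$statistic, 4), ", df ", signif(x$df, 4), ", p ",
        signif(x$p, 4), ", n ", x$n, "\n", sep = "")
  }
  invisible(x)
}

#' Broom-style tidiers for comparison objects
#'
#' @param x a `motor_comparison`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method tidy motor_comparison
#' @export
tidy.motor_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, method = x$method, estimate = x$estimate,
                 statistic = x$statistic, df = x$df, p.value = x$p, n = x$n,
                 conf.low = x$conf_low, conf.high = x$conf_high,
                 suppressed = x$suppressed)
}

#' @rdname tidy.motor_comparison
#' @method glance motor_comparison
#' @export
glance.motor_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, p.value = x$p, n = x$n,
                 suppressed = x$suppressed)
}

#' Paired baseline-versus-meal comparison
#'
#' Two-sided paired t test on subjects with both baseline and post-meal
#' measurements (df = n - 1). Comparisons with fewer than 5 complete pairs
#' are suppressed (no p value is reported), following the small-sample
#' reporting rule.
#'
#' @param baseline,post paired numeric vectors (same subjects, same order).
#' @param metric metric name carried in the result.
#' @return a `motor_comparison`.
#' @export
paired_compare <- function(baseline, post, metric = "metric") {
  if (length(baseline) != length(post))
    stop("baseline and post must be the same length", call. = FALSE)
  ok <- stats::complete.cases(baseline, post)
  x <- baseline[ok]; y <- post[ok]
  n <- length(x)
  if (n < 5)
    return(new_comparison(metric, "paired_t", n = n, suppressed = TRUE,
                          note = "n < 5"))
  if (stats::sd(y - x) == 0)
    return(new_comparison(metric, "paired_t", estimate = mean(y - x),
                          statistic = 0, df = n - 1, p = 1, n = n))
  tt <- stats::t.test(y, x, paired = TRUE)
  new_comparison(metric, "paired_t", estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = n,
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

#' Independent-samples baseline comparison between groups
#'
#' Two-sided independent t test (equal variances, as in classical cohort
#' tables).
#'
#' @param x,y numeric vectors for the two groups.
#' @param metric metric name.
#' @return a `motor_comparison`.
#' @export
independent_compare <- function(x, y, metric = "metric") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- min(length(x), length(y))
  if (n < 5)
    return(new_comparison(metric, "independent_t", n = length(x) + length(y),
                          suppressed = TRUE, note = "n < 5"))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  new_comparison(metric, "independent_t",
                 estimate = unname(diff(rev(tt$estimate))),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = length(x) + length(y),
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
}

#' Compare pattern presence within or between groups
#'
#' `mode = "within"`: exact McNemar test on paired presence flags
#' (before/after meal, same subjects) - the two-sided exact binomial on the
#' discordant pairs, `p = min(1, 2 * pbinom(min(b, c), b + c, 1/2))`, `p = 1`
#' when there are no discordant pairs. `mode = "between"`: two-sided Fisher
#' exact test on the 2x2 presence table of two independent groups.
#' Comparisons with fewer than 5 subjects (pairs, or in either group) are
#' suppressed.
#'
#' @param x,y logical vectors: paired baseline/post flags (`within`) or the
#'   two groups' flags (`between`).
#' @param mode `"within"` or `"between"`.
#' @param metric metric name.
#' @return a `motor_comparison`.
#' @export
presence_compare <- function(x, y, mode = c("within", "between"),
                             metric = "presence") {
  mode <- match.arg(mode)
  if (!all(x %in% c(TRUE, FALSE)) || !all(y %in% c(TRUE, FALSE)))
    stop("presence flags must be logical", call. = FALSE)
  if (mode == "within") {
    if (length(x) != length(y))
      stop("paired flags must be the same length", call. = FALSE)
    n <- length(x)
    if (n < 5)
      return(new_comparison(metric, "mcnemar_exact", n = n,
                            suppressed = TRUE, note = "n < 5"))
    b <- sum(x & !y); c <- sum(!x & y)
    p <- if (b + c == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    new_comparison(metric, "mcnemar_exact", estimate = c - b,
                   statistic = min(b, c), df = NA_real_, p = p, n = n)
  } else {
    if (length(x) < 5 || length(y) < 5)
      return(new_comparison(metric, "fisher_exact",
                            n = length(x) + length(y), suppressed = TRUE,
                            note = "n < 5"))
    tab <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
    ft <- stats::fisher.test(tab)
    new_comparison(metric, "fisher_exact", estimate = unname(ft$estimate),
                   statistic = NA_real_, df = NA_real_, p = ft$p.value,
                   n = length(x) + length(y),
                   conf_low = ft$conf.int[1], conf_high = ft$conf.int[2])
  }
}

#' Baseline-adjusted group comparison of post-meal values
#'
#' Regression of the post-meal value on subject group adjusted for the
#' baseline value: a two-covariate linear model for continuous metrics, a
#' two-covariate logistic model (maximum likelihood) for presence flags.
#' Reports the group coefficient, its confidence interval and p value.
#' Complete separation in the logistic case is flagged and the p value
#' suppressed.
#'
#' @param post post-meal values (numeric, or logical when `binary`).
#' @param baseline baseline values.
#' @param group factor/character of group membership (2 levels; the
#'   coefficient is for the second level vs the first).
#' @param binary logistic (`TRUE`) or linear (`FALSE`) model.
#' @param metric metric name.
#' @return a `motor_comparison`; the fitted model is attached as attribute
#'   `"model"`.
#' @export
baseline_adjusted_compare <- function(post, baseline, group, binary = FALSE,
                                      metric = "metric") {
  ok <- stats::complete.cases(post, baseline, group)
  d <- data.frame(post = post[ok], baseline = baseline[ok],
                  group = factor(group[ok]))
  n <- nrow(d)
  if (nlevels(d$group) != 2)
    stop("group must have exactly 2 levels", call. = FALSE)
  if (binary) {
    d$post <- as.integer(d$post)
    fit <- suppressWarnings(stats::glm(post ~ group + baseline, data = d,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients[2, ]
    separated <- any(fit$fitted.values > 1 - 1e-8 |
                       fit$fitted.values < 1e-8) || abs(co[1]) > 15
    if (separated)
      return(structure(new_comparison(metric, "baseline_adjusted_logistic",
                                      estimate = co[1], n = n,
                                      suppressed = TRUE,
                                      note = "separation"),
                       model = fit))
    ci <- co[1] + c(-1, 1) * stats::qnorm(0.975) * co[2]
    cmp <- new_comparison(metric, "baseline_adjusted_logistic",
                          estimate = co[1], statistic = co[3],
                          df = fit$df.residual, p = co[4], n = n,
                          conf_low = ci[1], conf_high = ci[2])
  } else {
    fit <- stats::lm(post ~ group + baseline, data = d)
    co <- summary(fit)$coefficients[2, ]
    ci <- stats::confint(fit)[2, ]
    cmp <- new_comparison(metric, "baseline_adjusted_linear",
                          estimate = co[1], statistic = co[3],
                          df = fit$df.residual, p = co[4], n = n,
                          conf_low = ci[1], conf_high = ci[2])
  }
  structure(cmp, model = fit)
}

#' Export a cohort summary table
#'
#' Writes the classical cohort table: one row per metric, one column per
#' group-phase cell holding `mean +/- SD (n)` for continuous metrics and
#' `k (pct%) (n)` for presence flags, in a deterministic row order.
#'
#' @param summaries tibble of per-session summaries (rows = subject-phase;
#'   must carry `subject_id`, `group`, `phase` plus metric columns).
#' @param out output TSV path, or `NULL` to skip writing.
#' @return the formatted table (tibble), invisibly when written.
#' @export
export_table <- function(summaries, out = NULL) {
  metric_cols <- setdiff(names(summaries),
                         c("subject_id", "group", "phase", "analyzed_s"))
  cells <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value",
                        values_transform = as.numeric) |>
    dplyr::group_by(.data$metric, .data$group, .data$phase) |>
    dplyr::summarise(cell = format_cell(.data$value, .data$metric[1]),
                     .groups = "drop") |>
    tidyr::unite("col", "group", "phase") |>
    tidyr::pivot_wider(names_from = "col", values_from = "cell")
  cells <- cells[order(match(cells$metric, metric_cols)), ]
  if (!is.null(out)) {
    readr::write_tsv(cells, out)
    return(invisible(cells))
  }
  cells
}

format_cell <- function(v, metric) {
  n <- sum(!is.na(v))
  if (!n) return("-")
  if (grepl("present$", metric)) {
    k <- sum(v == 1, na.rm = TRUE)
    sprintf("%d (%.1f%%) (%d)", k, 100 * k / n, n)
  } else if (n == 1) {
    sprintf("%.1f (1)", mean(v, na.rm = TRUE))
  } else {
    sprintf("%.1f ± %.1f (%d)", mean(v, na.rm = TRUE),
            stats::sd(v, na.rm = TRUE), n)
  }
}
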