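---
title: "Detecting colonic motor patterns in high-resolution manometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting colonic motor patterns in high-resolution manometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colomotor)
```

## The problem

High-resolution colonic manometry (HRCM) records intraluminal pressure along
the colon with a catheter carrying many closely spaced sensors — here the
standard geometry of 36 solid-state sensors at 1-cm spacing, covering about
35 cm of the transverse–descending colon, with sensor P1 most distal (closest
to the anal verge) and P36 at the catheter tip. Clinical analysis of these
recordings has traditionally been done by eye on spatiotemporal pressure
maps. `colomotor` automates that analysis: it detects and classifies the
recurring motor patterns of the human colon, screens out pressure changes of
abdominal (non-colonic) origin, quantifies haustral activity, and produces
the per-session and cohort summary statistics used in clinical motility
studies.

The pattern taxonomy and its numeric criteria are the ones established in
the HRCM literature:

* **Simultaneous pressure wave (SPW)** — a transient pressure rise of at
  least 2.5 s duration and at least 5 mmHg amplitude appearing at once over
  most or all sensors. A typical SPW rises ~20 mmHg in ~8 s and returns to
  baseline irregularly over ~12 s, often with smaller transients
  superimposed on the decay limb. SPWs are propulsive: they associate with
  gas expulsion and with relaxation of the internal anal sphincter.
* **Antegrade / retrograde propagating wave (APW / RPW)** — 5–100 mmHg over
  three or more adjacent sensors with a measurable propagation velocity.
  On a 1-cm array, velocity can be resolved only up to about 7 cm/s; faster
  fronts are indistinguishable from simultaneous and are classified SPW.
* **High-amplitude propagating wave (HAPW)** — at least 100 mmHg in at
  least 3 sensors; the most forceful propulsive pattern.
* **Isolated pressure transient** — a short-lasting rise of at least
  5 mmHg confined to one sensor, not connected to pressure changes in
  adjacent sensors; amplitudes span roughly 5–230 mmHg.
* **Haustral-boundary pressure transients** — isolated transients recurring
  at sensors 3–5 cm apart (occasionally up to 8 cm), often strikingly
  rhythmic at ~3 cycles/min, marking the contracted boundaries of haustra.
* **Intrahaustral segmentation and synchronized haustral pressure waves
  (SHPWs)** — within one haustrum (3–5 sensors), erratic uncoordinated
  activity alternates abruptly with epochs in which the ~3 cycles/min
  rhythm is coherent across the window and propagates at ~2 ± 1 cm/s in
  antegrade, retrograde or mixed direction; SHPW episodes last 2–10 min and
  occur a few times per session or not at all.

## Detection pipeline

`detect_events()` runs the full chain:

1. **Baseline.** Each sensor's trace is smoothed with a 0.5-s moving
   average and referenced to a rolling 10th-percentile baseline (60-s
   window, evaluated on a 1-s grid and interpolated). The percentile
   baseline ignores transients shorter than about half the window while
   tracking slow drift. The short pre-smoother is what makes the 5-mmHg
   threshold usable at realistic noise levels: with ~1 mmHg sensor noise an
   unsmoothed trace would occasionally cross 5 mmHg on single samples,
   while after smoothing a crossing requires a genuine pressure event.
   All amplitudes are pressure minus baseline, which makes every downstream
   decision invariant to constant pressure offsets.
2. **Per-sensor transients.** Excursions reaching 5 mmHg are delimited at
   the 25%-of-peak crossings (a noise-robust stand-in for the "initial
   rise"); same-sensor excursions closer than 2 s merge; excursions
   narrower than 0.5 s at the 25% level are rejected as noise.
3. **Candidate events.** Transients on adjacent sensors chain into one
   candidate when their onsets fall within 2 s per step, or when their
   intervals overlap by at least half the shorter interval. The overlap
   clause exists because onset jitter under noise occasionally pushes two
   members of a genuinely simultaneous wave just past the onset window,
   which would otherwise fragment one SPW into pieces; overlapping
   excursions on adjacent sensors are never independent events.
4. **Velocity.** For candidates on 3+ sensors, onset time is regressed on
   sensor position: the slope magnitude comes from the Theil–Sen estimator
   (robust to a single aberrant onset) and a least-squares t-test supplies
   the flatness check. Velocity is signed, positive toward the anus. A
   fitted |velocity| above 7 cm/s, or a trend not distinguishable from
   flat (p ≥ 0.05), is reported as simultaneous.
5. **Artifact screen.** Global simultaneous pressurizations covering most
   of the array are checked against the sphincter rule (below) before they
   can enter the taxonomy; events whose onset falls in an annotated
   artifact interval are dropped outright.
6. **Classification** in fixed order — single sensor → isolated transient;
   ≥ 3 sensors at ≥ 100 mmHg with determinate velocity → HAPW;
   simultaneous, ≥ 2.5 s and span ≥ 14 cm → SPW; determinate velocity over
   ≥ 3 adjacent sensors → APW/RPW; anything else dissolves into isolated
   transients. The order makes the classes mutually exclusive and
   exhaustive. The 14-cm SPW span floor operationalizes "most or all
   sensors": it equals the smallest span reported for real SPWs, and is
   configurable. Single-sensor events that lie inside the time–sensor
   footprint of a classified multi-sensor wave (e.g. the superimposed peaks
   on an SPW decay limb) are absorbed into that wave rather than reported
   as isolated transients, since by definition an isolated transient is not
   connected to other pressure changes.
7. **Parameters.** Duration is the median over member sensors of
   offset − onset (which sensor the manual analysis used is not knowable;
   the median is the least fragile choice and both per-sensor values are
   retained in the transient table). Span is (last − first sensor) ×
   spacing. Mean amplitude follows the "cursor at the center" convention:
   baseline-subtracted pressure at the event's temporal midpoint averaged
   over member sensors.

## Artifact screening

Coughs, body shifts, talking and drinking raise abdominal pressure and
appear in every sensor at once, so they can masquerade as SPWs. Two
defenses are used:

* **Annotations.** Contemporaneous observer annotations become exclusion
  intervals (±3 s; ±10 s for body shifts and repositioning). Gas expulsion
  is *not* an artifact — it accompanies SPWs and is used for the
  association metric instead. Talk (~5 mmHg) and drink (~10 mmHg)
  signatures are too weakly characterized for reliable automatic
  detection and are handled only via annotations.
* **The sphincter rule.** Abdominal pressurizations *increase* internal
  anal sphincter pressure, whereas an approaching SPW is *preceded* by
  sphincter relaxation. When the two most distal channels carry resting
  tone above 20 mmHg (a sphincter pull-back placement), a global
  simultaneous event with a sphincter rise of ≥ 5 mmHg is ruled abdominal
  and one with a dip ≥ 20% below local tone starting at or before arrival
  is ruled colonic. The +5 mmHg rise criterion is this package's
  operationalization — the source literature states the physiology but no
  number. Without a sphincter channel, a morphology fallback applies:
  global events shorter than 2.5 s with sub-second rise (a cough
  signature, shorter than any SPW can be) are abdominal.

## Haustral analysis

Per-sensor transient trains are binarized into 1-s bins; the periodogram
peak in the 1–6 cycles/min band is tested against the 95th percentile of a
shuffled-train null (shuffling preserves the rate and destroys the timing),
so a Poisson train of the same rate is called rhythmic only at the ~5%
false-positive level. Boundary sensors are local rate maxima at least 3×
the mean rate of intervening sensors; a boundary set is accepted when ≥ 3
maxima space regularly (spacing CV ≤ 0.35), which admits the common 3–5 cm
spacings as well as regular 8-cm sets. Boundary sets persist on the same
sensors for tens of minutes; `boundary_persistence()` measures this by
re-detecting the set in consecutive 30-min blocks, and `analyze_haustral()`
drives the whole stage end to end.

Within a haustral window (2–5 adjacent sensors; windows between detected
boundaries, or sliding 5-sensor windows when none exist), 60-s blocks are
labeled by band-passing the 1-Hz-averaged pressures to 1–6 cycles/min and
computing the mean pairwise maximum cross-correlation over lags up to 10 s:
r̄ ≥ 0.6 → synchronized (with velocity and direction from the pairwise
lags), r̄ < 0.6 with activity present → segmentation, under 0.5
transients/min → quiescent. The 0.6 threshold and 10-s lag bound were
calibrated on the synthetic generator and are exposed as arguments; 60-s
blocks are the shortest resolving ≥ 3 cycles of a 3 cycles/min rhythm.
Runs of synchronized blocks of ≥ 2 min merge into SHPW episodes; direction
is antegrade/retrograde when ≥ 70% of block velocity signs agree,
otherwise mixed (the usual case in practice — the 70% cut is this
package's operationalization of "almost always of mixed direction").
Episode frequency uses a zero-padded periodogram so that a single rhythm's
peak is located well below the 1-cycle/min bin spacing of a 60-s block.

## Cohort statistics

`summarize_session()` produces the per-phase metric block: occurrence per
30 min of unmasked time; maximum sustained frequency (the highest
frequency over ≥ 3 consecutive inter-onset intervals with CV ≤ 0.25 — the
"sustained rhythmicity" criterion made explicit); mean duration, distance
and amplitude; the isolated-transient block (max amplitude; % of 36
sensors involved — the denominator stays 36 by convention even with
malfunctioning sensors; % time as summed transient durations over unmasked
phase time averaged across functional sensors; and the three amplitude
categories, which may sum to more than 100% because one sensor can record
in several); and HAPW/SHPW presence flags.

Comparisons follow standard clinical practice: paired t within subjects,
independent t between groups at baseline, exact McNemar (two-sided
binomial on discordant pairs — exact rather than chi-square because
cohorts of ~15 are typical) and Fisher exact for presence flags, and
baseline-adjusted linear/logistic regression for post-meal group
comparisons (post-meal value ~ group + baseline). Any comparison with
fewer than 5 subjects is suppressed rather than reported, and complete
separation in the logistic model is flagged with the p value withheld.
No multiplicity correction is applied, matching the descriptive reporting
convention of the field. Age adjustment is deliberately omitted.

## The synthetic generator

Because clinical HRCM recordings are not publicly deposited, every stage is
validated against `generate_recording()` / `benchmark_recording()`, which
emulate the published waveforms with exact ground truth: SPW trains
(half-cosine rise to an exact peak, exponential decay scaled to fall below
5% of peak within the stated decay time, optional superimposed transients
confined to the decay limb), propagating waves with signed velocity and
per-sensor onset offsets, isolated transients with log-normal amplitudes
truncated to 5–230 mmHg (the source range; the log-normal shape is a
modeling choice, as no amplitude distribution is reported),
haustral-boundary rhythms, intrahaustral segmentation/synchronized
schedules, the four artifact signatures, a sphincter channel pair
(40 mmHg tone, relaxation beginning 2 s before SPW arrival, pressurization
during coughs and body shifts — modeled on the two most distal channels),
per-phase rate multipliers emulating the gastro-colonic meal response
(rates change after a meal; the multiplier is mechanism-neutral), and
i.i.d. Gaussian sensor noise (default SD 1 mmHg; no published noise
characterization exists, so a single global additive model is used).
Everything is deterministic under a fixed seed.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: respiration and slow tonic changes,
correlated or heavy-tailed sensor noise, catheter migration, genuinely
overlapping waves (two patterns traversing the same sensors at the same
moment are ambiguous even to a human scorer; the benchmark lays events on
a jittered non-overlapping grid), and the biomechanics linking contraction
to pressure. Detection quality on real recordings must be expected to be
lower than the ≥ 0.9 per-class precision/recall measured on the benchmark.

## Numerical choices and degenerate inputs

Sampling rate defaults to 10 Hz (no acquisition rate is published for this
probe; 10 Hz resolves 2.5-s events and 7 cm/s onset staircases at 1-cm
spacing) and is configurable throughout. Velocity ties: a perfectly flat
onset fit (zero variance) yields an undefined slope t-test, which is
treated as flat, i.e. simultaneous. Candidates on fewer than 3 sensors
have undefined velocity and can only be isolated transients. An all-NA
trace is an error; malfunctioning sensors are masked out before detection.
Phase windows are half-open `[start, end)`; fully masked phases report
zero analyzed time and undefined per-time metrics. Validation problem
sizes (600–1200-s sessions, 20-seed replications, 1000-replicate null
calibrations) were chosen as the smallest giving stable estimates of the
quantities under test.

## Worked example

```{r example, eval = FALSE}
out <- benchmark_recording(duration_s = 900, seed = 1, noise_sd = 1)
events <- detect_events(out$recording, out$annotations)
dplyr::count(events, kind)
summarize_session(events, out$recording)
autoplot(out$recording, 0, 300)
```

## Known limitations

The SPW span floor (14 cm) and the synchrony threshold (r̄ ≥ 0.6) are
calibrated defaults, not published constants; both are arguments. The
sphincter rule requires a pull-back placement; without it, only the
morphology fallback and annotations protect against abdominal events.
Whether an SHPW may span two haustra is unsettled in the literature; the
window is capped at 5 sensors by default and configurable. Occurrence
denominators assume artifacts are annotated or detected; unannotated talk
and drink events are not found automatically. The package targets
stationary ~90–120-min sessions, not 24-h ambulatory recordings, and
assumes uniform sensor spacing.
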