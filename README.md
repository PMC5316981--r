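# colomotor

Automated detection, classification and quantification of colonic motor
patterns in high-resolution colonic manometry (HRCM) — intraluminal
pressure recorded by a catheter with 36 solid-state sensors at 1-cm
spacing along the transverse–descending colon. The package is written for
gastrointestinal motility researchers and clinical physiologists who
currently classify these recordings by eye on spatiotemporal pressure
maps.

## What it computes

Given a sensors × time pressure matrix (mmHg), an annotation log and
phase windows (baseline / meal / postprandial), `colomotor`:

* detects per-sensor pressure transients against a rolling
  10th-percentile baseline (threshold ≥ 5 mmHg, onsets at 25% of peak);
* chains them into multi-sensor events and estimates signed propagation
  velocity *v* by a robust (Theil–Sen) fit of onset time against sensor
  position, reporting fronts with |v| > 7 cm/s — the resolution bound of
  a 1-cm array — as *simultaneous*;
* classifies events into the standard taxonomy:
  * **SPW** (simultaneous pressure wave): simultaneous, duration ≥ 2.5 s,
    amplitude ≥ 5 mmHg, spanning most of the array;
  * **APW / RPW**: antegrade (*v* > 0, toward the anus) or retrograde
    propagating wave, 5–100 mmHg over ≥ 3 adjacent sensors;
  * **HAPW**: ≥ 100 mmHg in ≥ 3 sensors;
  * **isolated pressure transient**: single-sensor, unconnected to
    adjacent-sensor activity;
* screens abdominal-pressure artifacts (cough, body shift, talk, drink)
  using annotation intervals and the internal-anal-sphincter rule —
  abdominal events *pressurize* the sphincter while approaching SPWs are
  *preceded by sphincter relaxation*;
* quantifies haustral activity: rhythmic boundary transients at sensors
  3–8 cm apart (~3 cycles/min, periodogram + shuffled-train null),
  and intrahaustral windows labeled segmentation / synchronized /
  quiescent by band-limited cross-correlation (r̄ ≥ 0.6 over lags ≤ 10 s),
  with synchronized haustral pressure wave (SHPW) episodes of ≥ 2 min;
* builds per-subject, per-phase summaries (occurrence per 30 min of
  artifact-free time, maximum sustained frequency, duration, distance,
  amplitude, isolated-transient metrics, HAPW/SHPW presence) and the
  cohort comparisons: paired and independent t tests, exact McNemar,
  Fisher exact, and baseline-adjusted linear/logistic regression, with
  n < 5 comparisons suppressed.

A fully ground-truthed synthetic generator (`generate_recording()`,
`benchmark_recording()`) reproduces every published waveform, rhythm,
artifact signature and sphincter behavior, so the whole pipeline is
testable without patient data.

## Worked example

```r
library(colomotor)

out <- benchmark_recording(duration_s = 900, seed = 1, noise_sd = 1)
events <- detect_events(out$recording, out$annotations)
dplyr::count(events, kind)
#> # A tibble: 5 × 2
#>   kind                   n
#>   <chr>              <int>
#> 1 APW                    2
#> 2 HAPW                   2
#> 3 RPW                    3
#> 4 SPW                    8
#> 5 isolated_transient    10

summary <- summarize_session(events, out$recording)
round(summary$spw_per30, 1)      # SPW occurrence per 30 min: 16
round(summary$spw_duration_s, 1) # mean SPW duration (s): 17.4
summary$spw_distance_cm          # mean SPW propagation distance (cm): 35
```

The 25 detected events are exactly the 25 the generator injected, class
for class. A 35-cm propagation distance means the SPWs covered the full
sensor array, and the ~17-s duration reflects the canonical ~8-s rise +
~12-s decay morphology measured between the 25%-of-peak crossings.
`autoplot(out$recording, 0, 300)` draws the spatiotemporal map (distal
sensors at the bottom) on which these patterns are visible as vertical
bands.

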