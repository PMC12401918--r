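---
title: "Scoring behavioral drift in smart-home activity logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring behavioral drift in smart-home activity logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homedrift)
library(dplyr)
```

Ambient sensors in a home record a stream of timestamped events; when the
stream is annotated with activity labels (`Sleep`, `Cook_Breakfast`,
`Bed_Toilet_Transition`, ...) bracketed by `begin`/`end` markers, it
becomes a longitudinal record of a resident's daily routine. `homedrift`
quantifies how far any given day departs from that resident's own
baseline, on two complementary axes: the composition of the daytime
activity budget, and the structure of the night's sleep. This vignette is
the package's account of the model, its parameters and defaults, the
synthetic generator used for validation, and the numerical conventions
that make results reproducible.

## The activity deviation index

A day's labeled intervals are summed per activity and normalized to
proportions $A_i = d_i / \sum_j d_j$ of that day's total *labeled* time.
Unlabeled time is excluded from the denominator: proportions then sum to
exactly 1 on every scored day, which makes any two days (and the
reference) directly comparable as distributions. Days with zero labeled
time cannot be normalized; they are excluded and reported rather than
scored.

The reference routine $R_i$ is the pooled mean time budget: the mean daily
seconds of activity $i$ over the baseline days (absent activities counting
as zero), divided by the sum of those means across activities. This
normalization guarantees $\sum_i R_i = 1$ exactly. An alternative —
averaging each day's proportions — is available via
`build_reference_routine(method = "mean_proportion")`; the two differ only
when the total labeled time varies across days, in which case the pooled
form weights long days more. The pooled form is the default because it
represents the *time budget* of a typical day rather than the average of
compositions. By default the reference pools all available days (the mean
routine); `baseline_days = k` restricts it to the first $k$ days when an
early clean baseline is preferable to a contaminated global mean.

The index itself is

$$\mathrm{WADI} = \sum_i w_i\,|A_i - R_i|,$$

taken over the union of the day's and the reference's activities, absent
entries set to 0 — an activity that disappears from a day is a deviation,
not a missing value. The importance weights $w_i \ge 0$ are supplied by
the analyst (sleep and self-care conventionally outweigh leisure);
`validate_weights()` enforces $\sum w_i = 1$ in strict mode and only warns
in lax mode, because partially specified weight sets (the remaining
activities implicitly at zero weight) are common in practice and
analytically harmless: the index is then simply a weighted L1 distance
over the weighted subset. When no weights are given, `wadi_scores()` uses
equal weights $1/n$ over the reference activities, a neutral choice that
makes the index $1/n$ times the total variation distance's L1 form.

Properties worth knowing: the index is symmetric in day and reference;
it is zero iff every positively weighted activity matches; and it is
bounded by $\sum_i w_i$ (so by 1 under strict weights).

## Sleep metrics

Each night (noon-anchored: a session that wraps midnight belongs to the
evening's date, the standard actigraphy convention) is reduced to onset
$O$ in clock hours, total sleep $D$ in seconds, and interruption count
$I$. Interruptions default to the count of `Bed_Toilet_Transition` spans
inside the session — the one interruption signal an ambient-sensor
deployment reliably labels — with gap-based counting (inter-sleep gaps of
at most 2 h) available as an alternative for corpora lacking that label.

The reference is built from the session set: $R_O$ is the *circular* mean
of onsets, $R_D$ the mean duration, $\sigma_D$ the population standard
deviation of durations, and $\sigma_O$ a circular dispersion of onsets.
For $\sigma_O$ we use the angular deviation $\sqrt{2(1-\bar R)}$ (with
$\bar R$ the mean resultant length) mapped to hours. Two reasons: a naive
standard deviation of clock hours explodes for onsets straddling midnight
(23:30 and 00:30 would yield a 12 h mean and huge spread), and the angular
deviation is bounded (about 5.4 h at uniform scatter), keeping the
consistency index below meaningful.

The four nightly metrics are

* **onset deviation** $\mathrm{SOD} = \min(|O-R_O|,\,24-|O-R_O|)$, the
  circular clock distance in hours, in $[0, 12]$;
* **duration deviation** $\mathrm{SDD} = |D-R_D|/3600$ hours;
* **interruption index** $\mathrm{SII} = I/D_\mathrm{hours}$, events per
  hour of sleep (undefined for zero-duration nights, which are excluded
  and reported);
* **consistency** $\mathrm{SCI} = \max(0,\,1-\sigma_O/24-\sigma_D/R_D)$,
  a property of the reference period, identical for every night scored
  against it.

They aggregate to $\mathrm{SDP} = w_1\mathrm{SOD} + w_2\mathrm{SDD} +
w_3\mathrm{SII} + w_4(1-\mathrm{SCI})$, lower is better. The four terms
carry different native units (hours, hours, per-hour, unitless) and are
summed without renormalization — that is the score's printed form, and
users should read the weights as unit conversions: with the default equal
weights (0.25 each), one extra hour of onset deviation, one hour of
missing sleep, and four extra awakenings per hour are exchangeable. Any
application with a principled exchange rate should set the weights
accordingly (`sdp_weights()`).

## Flagging

A day is anomalous when its score strictly exceeds a threshold; ties are
not flagged. Two threshold modes:

* **fixed** — defaults 0.02 (activity) and 0.4 (sleep), the conventional
  boundaries between stable and disrupted regimes for these indices;
* **dynamic** — $\mathrm{mean} + \alpha\cdot\mathrm{sd}$ of the score
  history, with the *population* standard deviation (a documented, fixed
  choice that makes thresholds bit-stable). $\alpha$ (default 2) scales
  conservativeness, and flagged sets are nested in $\alpha$: raising it
  can only unflag. By default the statistics are computed over the whole
  score series (global mode); `threshold_config(window = k)` switches to
  a trailing window of the $k$ scores preceding each day, which adapts to
  slow drift and does not let a day's own outlying score raise its own
  threshold. Days with fewer than two prior scores are left unflagged in
  rolling mode.

A caution that falls straight out of the arithmetic: a global
mean-plus-sigma threshold is only as good as the score history is clean.
A few extreme outliers (say, 6 h onset shifts) inflate both the mean and
the sd enough that *moderate* anomalies — a night with five extra
awakenings, scoring ~0.28 against a ~0.12 baseline — fall below the
threshold and are missed. The rolling mode recovers them:

```{r rolling}
sim <- simulate_days(routine_spec(activity_cv = 0, onset_sd = 0,
                                  duration_sd = 0, interruption_rate = 0,
                                  seed = 7), 30)
inj <- as.Date("2016-01-01") + c(4, 12, 20, 8, 25)
pert <- inject_anomalies(sim, anomaly_plan(
  inj, c(rep("onset_shift", 3), rep("fragmentation", 2)),
  magnitude = c(6, 6, 6, 5, 5)))
sessions <- extract_sleep_sessions(pair_activity_intervals(pert$events))

global <- sdp_scores(sessions, threshold = threshold_config("dynamic", alpha = 1))
rolling <- sdp_scores(sessions, threshold = threshold_config("dynamic", alpha = 1,
                                                             window = 7))
sort(global$day[global$flagged])   # misses the two fragmented nights
sort(rolling$day[rolling$flagged]) # recovers all five injected days
```

## The synthetic home

The generator exists so that every scoring stage can be validated against
ground truth without external corpora. Its model is deliberately minimal
and stated here in full:

* **daytime activities** are scheduled back to back from 08:00 with
  10-minute gaps; each activity's daily duration is log-normal with the
  spec's mean and coefficient of variation (log-normal for positivity;
  cv 0 degenerates to identical days);
* **sleep onset** is wrapped-normal on the 24 h circle around
  `onset_mean` (an onset drawn before noon starts the session after
  midnight, so the noon anchor keeps the night on the evening's date);
* **total sleep** is normal, truncated at 10 minutes;
* **interruptions** are Poisson; each inserts a 600 s wake gap into the
  sleep block, with a `Bed_Toilet_Transition` span occupying its middle,
  *extending* the session span without reducing total sleep — the sampled
  duration parameter stays interpretable as true sleep time.

Defaults (onset 22:30 ± 0.5 h, 8 h ± 45 min of sleep, one interruption
per night, 20% day-to-day variation in the activity budget) describe a
reasonably regular older adult. The truth table is rendered into events
deterministically, so the same spec and seed give byte-identical streams,
and `inject_anomalies()` — onset shifts, shortened or fragmented sleep,
cyclic permutation of the day's activity durations, night-time appliance
episodes — perturbs only the planned days, leaving every other day's
event lines untouched and recording a ground-truth sidecar.

What the generator does *not* emulate: unlabeled sensor physics (PIR
firing cascades, temperature drift), annotation noise (mislabeled or
missing markers), multi-resident interleaving, weekday/weekend structure,
or seasonal drift. Tests passing on this generator therefore demonstrate
the correctness of the *scoring pipeline* under a known behavioral model,
not robustness to the label quality of any real corpus.

Validation experiments in the test suite use 30-day cohorts (20 replicate
seeds for the noisy-recovery experiment) and 200-day runs for
distributional sanity of the generator itself; these sizes put Monte
Carlo error well below the effects being asserted while keeping the whole
suite fast.

## Numerical conventions and degenerate inputs

* All timestamps are parsed and rendered in UTC; clock arithmetic never
  crosses a DST boundary.
* Day attribution: activity aggregation splits days at midnight; sleep
  attribution uses the noon anchor; an interval crossing a boundary
  belongs wholly to the day containing its start.
* Begin/end pairing matches each `begin` to the next same-label `end`,
  closing nested same-label begins LIFO; unmatched markers are reported
  as orphans, never raised as errors.
* Zero-labeled-time days, sleepless nights and zero-duration sessions
  are excluded from scoring and surfaced in reports (`empty_days`,
  `missing_nights` attributes).
* Population (not sample) standard deviations throughout the thresholds
  and the sleep reference.
* Malformed log lines are collected with line numbers; a file more than
  half malformed is rejected as the wrong dialect.

## Limitations

The indices presume reliable activity annotation; they measure deviation
from an individual's own baseline and say nothing diagnostic by
themselves. The consistency term makes every night's sleep score share a
reference-level constant, so within-period contrast comes entirely from
onset, duration and interruptions. Heterogeneous units in the sleep
aggregate mean its absolute scale is convention-dependent; compare scores
only within a fixed weight setting. And a contaminated global reference
(or threshold history) biases both indices toward missing moderate
anomalies — prefer a clean baseline window and the rolling threshold when
anomalies are expected to be frequent or extreme.
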