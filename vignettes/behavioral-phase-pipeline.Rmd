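---
title: "Passive behavioral features and lockdown phase comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive behavioral features and lockdown phase comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the pipeline measures

Continuously collected smartphone and wearable data let us quantify, day by
day, how a cohort's behavior changes around a major intervention such as a
national COVID-19 lockdown. `digiphase` derives nine daily features per
participant from seven raw sensor streams:

| Feature | Stream | Daily definition |
|---|---|---|
| `homestay_min` | GPS | minutes within 200 m of home, 8 AM–11 PM |
| `max_dist_m` | GPS | maximum distance from home, 8 AM–11 PM |
| `max_nearby` | Bluetooth | maximum hourly nearby-device count |
| `steps` | wearable steps | daily total |
| `hr_mean` | wearable heart rate | daily mean of raw readings |
| `sleep_min` | wearable sleep epochs | total light + deep + REM, 8 PM–11 AM |
| `bedtime_min` | wearable sleep epochs | first sleep epoch after 8 PM, minutes after 8 PM |
| `unlock_min` | phone state events | summed unlock→standby sessions |
| `social_min` | app events | summed durations of Social/Communication/Dating apps |

All features except the sleep pair use a 6 AM–6 AM "feature day", so a night
of phone use is attributed to the evening's calendar day. Timestamps are
local wall-clock time throughout; the pipeline performs no timezone
arithmetic because every analysis window is anchored in the participant's
local day.

A day with no data in a modality yields a missing value for that modality's
features rather than a zero — not wearing the wearable is not the same as
not sleeping.

## GPS processing

**Spurious-fix filter.** A fix is dropped when it differs from *both* its
original neighbours by more than 5 degrees in latitude or longitude
(`spurious_deg`). The per-axis reading is the simplest interpretation of a
"differs by more than five degrees" rule and is what the brute-force test
oracle implements as well; the threshold is configurable.

**Home inference.** Home is estimated nightly by DBSCAN over the fixes
between 8 PM and 4 AM (haversine metric), taking the mean coordinate of the
cluster containing the **last** fix of the night. The largest cluster can be
an evening venue; the last position before phones go quiet is more likely to
be home. DBSCAN parameters are not dictated by the measurement design, so we
chose `cluster_eps_m = 100` and `cluster_min_pts = 3`: at one fix per 5
minutes a full night has ~96 fixes, so requiring 3 core neighbours tolerates
heavy missingness; both are configurable. DBSCAN is implemented in-package
(O(n²) over one night's fixes, which is at most a few hundred points).
A day's home uses the night *ending* at that day's 4 AM, so the morning's
activity is referenced to where the participant actually woke up. If the
last night fix is a noise point, home — and therefore both GPS features —
is missing for that day.

**Homestay.** For each adjacent fix pair with both fixes within
`home_radius_m = 200` of home and a raw gap of at most `max_gap = 3600` s
(longer gaps are dominated by missing data rather than genuine dwell), the
pair's overlap with the 8 AM–11 PM stay window is added. Clipping pairs to
the window keeps homestay ≤ 900 minutes by construction. Distances use the
haversine formula with Earth radius 6,371,000 m.

**Obfuscation invariance.** Privacy-preserving location obfuscation adds a
participant-specific constant offset to every coordinate. Both GPS features
are defined relative to home, so a constant longitude offset (a rotation
about the Earth's axis) changes nothing; a constant latitude offset changes
the metric scale of longitude differences by the ratio of cosines, bounded
below 1% for offsets of 0.1 degrees at mid-latitudes. The test suite checks
both properties.

## Phase statistics

The unit of analysis is the **cohort's daily median** of each feature,
computed with linear-interpolation percentiles (type 7) over participants
with a value that day, and only when at least `min_n = 20` participants
contribute (days below the minimum are treated as missing).

Three phases are compared: *lockdown* (given), *prelockdown* (the same
number of days ending the day before the first restrictive measure), and
*baseline* (the same calendar period one year earlier by default, to
suppress seasonal variation; an explicit start date is required for cohorts
without a prior year of data — "stable" early data cannot be detected
automatically and is a study decision).

Per feature, a Kruskal-Wallis test (tie-corrected, chi-square reference)
compares the three phases. The nine omnibus p-values are corrected with
Benjamini–Yekutieli (valid under arbitrary dependence between features; the
correction family is the set of features actually tested). Only features
surviving that correction receive the three pairwise post hoc Dunn tests,
whose p-values are BY-corrected within the feature (m = 3) — classic
gatekeeping. Dunn z-statistics are signed as earlier-phase mean rank minus
later-phase mean rank, so a feature that *increases* during lockdown has a
*negative* prelockdown-vs-lockdown z. All tests are two-sided with α = 0.05
applied to corrected p-values.

**Subgroups.** During lockdown only, homestay and steps are compared
between subgroups (age < 45, gender, BMI < 25, degree, and young men vs
everyone else). The two subgroups' daily medians are paired by calendar day
and tested with a Wilcoxon signed-rank test (zeros dropped, mid-ranks,
exact null for ≤ 25 untied pairs, otherwise normal approximation with tie
and continuity corrections), reporting W = min(W⁺, W⁻); p-values are
BY-corrected across the 10 factor × feature combinations. A signed-rank
test on two *independent* subgroups is ambiguous; pairing by day is the
reading consistent with small W statistics on the order of the number of
days, and an unpaired rank-sum variant is available via
`subgroup_analysis(..., method = "rank_sum")`. The cohort-wide ≥ 20
participant rule is not imposed within subgroups (a 40-participant cohort
split two ways would never qualify); the per-day minimum is configurable.

## The synthetic cohort

No public dataset accompanies this kind of passive-monitoring study, so the
package ships a seeded generator whose *defaults are the study conditions*
for all validation:

* GPS on a 5-minute grid with configurable missingness (default 0.1) and
  10 m positional jitter; hourly Bluetooth scans (Poisson counts); heart
  rate at 60 s (a daily mean is insensitive to cadence, and 5 s sampling
  would only inflate files); 30 s sleep epochs; alternating unlock/standby
  events; categorised app events.
* Each participant-day draws behavioral *targets* (homestay hours, log-scale
  excursion distance, trips, steps, heart rate, sleep, bedtime, unlock and
  social time) from per-phase normal/lognormal distributions, with one
  multiplicative lognormal participant effect per mean (`heterogeneity`,
  default coefficient of variation 0.15). The distributions themselves are
  artifact choices — the study design implies none — and every parameter is
  configurable through `behavior_params()`.
* The lockdown-effect defaults shift the phases in the directions national
  lockdowns produced: homestay 8.5 → 12 h, excursion 3 → 1.2 km, steps
  8000 → 4500, nearby devices 6 → 2.5, heart rate 72 → 69 bpm, sleep
  7 → 7.7 h, bedtime 175 → 210 min after 8 PM, unlock 2 → 2.8 h, social use
  1 → 1.7 h. The null configuration makes the three phases identical.

**Why closure is exact.** GPS days are built as home dwell plus out-and-back
excursions whose away intervals are quantised to the fix grid and whose
interior fixes are clamped to at least 250 m from home (beyond the 200 m
radius), with the trip apex placed exactly at the drawn excursion distance.
Scheduled homestay therefore equals what the pair-gating extractor computes,
fix for fix, and the realised maximum distance is the apex fix's true
distance; the ground-truth table records realised values (the generator's
bookkeeping), so in noiseless settings every extracted feature matches
ground truth up to its discretisation step (one GPS period for homestay, one
epoch for sleep, exactly for counts and sums). This is deliberately *not* a
realistic human-mobility model — no Lévy flights, activity schedules or
multi-destination days — so passing closure shows the extractor implements
its stated rules, not that it is robust to every real-world trace shape.

`simulate_feature_table()` exposes the target-draw layer directly, which is
what the Monte-Carlo calibration studies use: a null-configured cohort (40
participants, three 30-day phases, 200 seeds) to confirm the BY-corrected
omnibus rejection rate stays at or below the nominal level, an
effect-configured cohort (100 seeds) to confirm all nine features come out
significant with the expected sign pattern, and shifted/null subgroup
configurations (100 seeds each) for the signed-rank tests. One subtlety:
with participant-level random effects, two finite subgroups differ
*persistently* across days even under a null configuration — the paired
signed-rank test then correctly rejects, because days are not exchangeable
between subgroups. The level check therefore uses `heterogeneity = 0`, the
configuration under which the day-level subgroup null actually holds. This
is a genuine caveat of day-paired subgroup testing on a finite cohort, not
an artifact of the generator.

## Numerical and degenerate-input choices

* All-identical samples: Kruskal-Wallis returns H = 0, p = 1 (the tie
  correction would otherwise divide by zero); identical subgroup series
  return W = 0, p = 1.
* Unknown sleep-stage labels map to `wake` (conservatively excluded from
  sleep totals, with a warning); unknown app categories count as
  non-social.
* Unlock sessions: repeated unlocks keep the first, a trailing unlocked
  state contributes nothing, and sessions above 4 h are discarded as missed
  standby events. Sessions spanning 6 AM belong to the day of the unlock.
* Percentiles: linear interpolation (type 7), recorded here because the
  convention is a genuine free choice.
* Problem sizes for the shipped validation runs (a 25 × 60-day closure
  cohort, 200/100/100 Monte-Carlo seeds at 40 participants × 90 days) were
  chosen so the full suite exercises every layer at cohort scale while
  staying comfortable to run repeatedly during development.

## Limitations

* The generator's behavioral distributions are plausible but invented; the
  pipeline's statistical power on real cohorts depends on real effect sizes
  and missingness patterns it does not emulate (device churn, server
  outages, seasonal drift).
* Sleep staging and step counting are taken as given inputs; the pipeline
  neither re-derives them from raw signals nor models their error.
* One home per participant-day: split residences, night shifts, or travel
  days violate the home-inference assumptions.
* The day-paired subgroup test inherits the caveat above: with few
  participants per subgroup, persistent between-participant differences are
  part of what it detects.
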