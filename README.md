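# digiphase

Digital phenotyping of behavioral change from passive smartphone and
wearable data.

Continuously collected sensor streams — GPS fixes, Bluetooth scans, step
counts, heart-rate readings, sleep epochs, phone unlock/standby events and
categorised app use — can show, day by day, how a cohort's behavior shifts
around an intervention such as a national COVID-19 lockdown. `digiphase`
implements the full pipeline for cohort studies of this kind:

1. **Feature extraction** — nine daily features per participant:
   homestay (minutes within 200 m of the nightly DBSCAN-inferred home
   location, 8 AM–11 PM), maximum distance from home, maximum number of
   nearby Bluetooth devices, total steps, mean heart rate, sleep duration
   and bedtime (8 PM–11 AM window), phone unlock duration (unlock→standby
   sessions, 4-hour cap) and social-app use (Social/Communication/Dating
   categories). Non-sleep features use a 6 AM–6 AM feature day; a day
   without data in a modality yields a missing value, not a zero.
2. **Cohort aggregation** — daily cross-participant median and quartiles
   per feature, computed only on days with ≥ 20 contributing participants.
3. **Phase statistics** — Kruskal-Wallis tests on the daily medians across
   *baseline* (same period one year earlier), *prelockdown* (same length,
   ending the day before the first restrictive measure) and *lockdown*,
   Benjamini–Yekutieli corrected across the nine features (m = 9); features
   surviving the correction receive post hoc Dunn tests, BY-corrected
   across the three phase pairs (m = 3). Dunn z is signed earlier-minus-
   later, so a feature that increases during lockdown has negative z.
   Subgroup contrasts (age < 45, gender, BMI < 25, degree, young men)
   compare day-paired subgroup daily medians of homestay and steps during
   lockdown with Wilcoxon signed-rank tests (W = min(W⁺, W⁻)), BY-corrected
   across the 10 combinations.
4. **Synthetic cohort generator** — a fully seeded simulator of all seven
   streams with known per-phase behavioral parameters and a realised
   ground-truth table, so every stage of the pipeline is testable without
   any private data.

## Worked example

Simulate a 40-participant cohort with lockdown-shifted behavior (Italy-like
windows: lockdown 2020-03-21 to 2020-05-09, first restriction 2020-03-08)
and test the phase contrasts:

```r
library(digiphase)
library(dplyr)

windows <- phase_windows("2020-03-21", "2020-05-09", "2020-03-08")
cfg <- sim_config(windows, n_participants = 40, seed = 1)
sim <- simulate_feature_table(cfg, behavior_params("lockdown"))

res <- phase_analysis(sim$features, windows)
filter(res, comparison == "prelockdown_vs_lockdown")
#> # A tibble: 9 × 6
#>   feature      comparison              statistic    p_raw    p_adj significant
#>   <chr>        <chr>                       <dbl>    <dbl>    <dbl> <lgl>
#> 1 homestay_min prelockdown_vs_lockdown     -8.50 1.85e-17 5.10e-17 TRUE
#> 2 max_dist_m   prelockdown_vs_lockdown      8.89 6.28e-19 3.45e-18 TRUE
#> 3 max_nearby   prelockdown_vs_lockdown      9.34 9.47e-21 2.60e-20 TRUE
#> 4 steps        prelockdown_vs_lockdown      8.73 2.59e-18 1.42e-17 TRUE
#> 5 hr_mean      prelockdown_vs_lockdown      8.88 6.82e-19 3.75e-18 TRUE
#> 6 sleep_min    prelockdown_vs_lockdown     -8.86 8.01e-19 4.41e-18 TRUE
#> 7 bedtime_min  prelockdown_vs_lockdown     -9.00 2.29e-19 1.26e-18 TRUE
#> 8 unlock_min   prelockdown_vs_lockdown     -9.11 8.04e-20 4.42e-19 TRUE
#> 9 social_min   prelockdown_vs_lockdown     -8.83 1.03e-18 5.67e-18 TRUE
```

Every feature differs significantly between prelockdown and lockdown, with
the sign pattern a lockdown produces: negative z (increase during lockdown)
for homestay, sleep, bedtime, unlock and social-app use; positive z
(decrease) for travelled distance, nearby devices, steps and heart rate.

Subgroup contrasts during lockdown, e.g. steps by BMI group:

```r
sg <- subgroup_analysis(sim$features, sim$metadata, windows)
filter(sg, feature == "steps", factor == "bmi")
#> # A tibble: 1 × 9
#>   feature factor comparison      statistic n_pairs direction   p_raw  p_adj significant
#>   <chr>   <chr>  <chr>               <dbl>   <int>     <dbl>   <dbl>  <dbl> <lgl>
#> 1 steps   bmi    low_vs_high_bmi       317      50        -1 0.00201 0.0222 TRUE
```

`direction = -1` says the low-BMI subgroup's daily median was below the
high-BMI subgroup's on most of the 50 paired lockdown days (this cohort was
simulated without a configured BMI effect; with 20-odd participants per
subgroup, persistent participant-level differences are part of what the
day-paired test detects — see the methods vignette).

To materialise actual sensor streams instead of feature draws, write a full
dataset (one `<pid>.<modality>.csv` per stream plus `metadata.csv` and
`ground_truth.csv`) and run the extractor on it:

```r
dir <- simulate_cohort(cfg, behavior_params("lockdown"), dir = "cohort_data")
features <- build_feature_table(dir)   # pid x date x nine features
daily <- cohort_daily(features)        # median/quartile series, n >= 20 rule
```

A thin command-line wrapper with `simulate` / `extract` / `analyze`
subcommands is installed at `inst/cli/digiphase.R`.

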