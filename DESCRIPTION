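Package: digiphase
Title: Digital Phenotyping Features and Lockdown Phase Comparison from
    Passive Smartphone and Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts nine daily behavioral features from passive smartphone
    and wearable sensor streams (GPS homestay and maximum distance from home
    via density-based home-location inference, Bluetooth nearby-device counts,
    step counts, mean heart rate, sleep duration, bedtime, phone unlock
    duration, and social-app use duration), aggregates them across a cohort as
    daily median/quartile series, and tests for behavioral change among
    baseline, prelockdown, and lockdown phases with Kruskal-Wallis and post hoc
    Dunn tests under Benjamini-Yekutieli correction, plus paired subgroup
    Wilcoxon signed-rank comparisons. Includes a seeded synthetic multimodal
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
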