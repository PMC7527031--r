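# Synthetic multimodal sensor cohort with known phase-dependent behavioral
# parameters. The generator has two layers sharing one set of daily draws:
#
#   * simulate_feature_table(): draws each participant's daily behavioral
#     targets (the ground truth) without materialising sensor streams --
#     used for Monte-Carlo calibration of the phase statistics.
#   * simulate_cohort() / simulate_participant(): additionally materialise
#     the seven raw sensor streams (GPS fixes on a 5-minute grid, hourly
#     Bluetooth scans, 30-second sleep epochs, unlock/standby events, ...)
#     so the whole extraction pipeline can be validated against the
#     generator's bookkeeping.
#
# GPS days alternate home dwell with out-and-back excursions whose away
# intervals are aligned to the fix grid and whose interior fixes are kept
# beyond the homestay radius, so scheduled homestay and the realised maximum
# distance are recovered exactly by the extractor in noiseless settings.

#' Per-phase behavioral parameters for the synthetic cohort
#'
#' One row per phase (`baseline`, `prelockdown`, `lockdown`). With
#' `effect = "lockdown"` the lockdown row shifts every feature in the
#' qualitative direction reported for national lockdowns (homestay, sleep,
#' bedtime, unlock and social use up; distance, nearby devices, steps and
#' heart rate down); with `effect = "null"` all three phases share the
#' baseline parameters.
#'
#' @param effect `"lockdown"` or `"null"`.
#' @return Tibble of class `behavior_params`, one row per phase.
#' @export
behavior_params <- function(effect = c("lockdown", "null")) {
  effect <- match.arg(effect)
  base <- tibble::tibble(
    phase = "baseline",
    homestay_h_mean = 8.5, homestay_h_sd = 1.5,
    excursion_logkm_mean = log(3), excursion_logkm_sd = 0.5,
    n_trips = 2,
    bt_rate = 6,
    steps_mean = 8000, steps_sd = 2000,
    hr_mean = 72, hr_sd = 2,
    sleep_h_mean = 7.0, sleep_h_sd = 0.7,
    bedtime_min_mean = 175, bedtime_min_sd = 30,
    unlock_h_mean = 2.0, unlock_h_sd = 0.5,
    social_h_mean = 1.0, social_h_sd = 0.3
  )
  pre <- dplyr::mutate(base, phase = "prelockdown")
  lock <- if (effect == "lockdown") {
    dplyr::mutate(base, phase = "lockdown",
                  homestay_h_mean = 12, excursion_logkm_mean = log(1.2),
                  n_trips = 1, bt_rate = 2.5,
                  steps_mean = 4500, steps_sd = 1500,
                  hr_mean = 69, sleep_h_mean = 7.7,
                  bedtime_min_mean = 210, unlock_h_mean = 2.8,
                  social_h_mean = 1.7, social_h_sd = 0.4)
  } else dplyr::mutate(base, phase = "lockdown")
  out <- dplyr::bind_rows(base, pre, lock)
  stopifnot(all(out$sleep_h_mean >= 3 & out$sleep_h_mean <= 14),
            all(out$homestay_h_mean >= 0 & out$homestay_h_mean <= 15),
            all(is.finite(unlist(out[-1]))))
  class(out) <- c("behavior_params", class(out))
  out
}

#' Simulation configuration
#'
#' @param windows Phase windows from [phase_windows()]; the simulated date
#'   range must span all three phases.
#' @param n_participants Number of participants (>= 1).
#' @param start,end Simulated date range; defaults to exactly the union of
#'   the phase windows.
#' @param seed Integer RNG seed; the whole simulation is a deterministic
#'   function of it.
#' @param gps_period GPS sampling period, seconds (nominal 5 minutes).
#' @param gps_missingness Probability that a scheduled GPS fix is dropped.
#' @param gps_jitter_m Positional noise sd, meters (0 for noiseless runs).
#' @param obfuscation Add a participant-specific constant offset (uniform in
#'   +/-0.1 degrees latitude, +/-0.5 degrees longitude) to every emitted
#'   fix, emulating privacy-preserving location obfuscation.
#' @param hr_period Heart-rate sampling period, seconds.
#' @param hr_sample_sd Within-day heart-rate sample noise, bpm.
#' @param epoch_len Sleep epoch length, seconds.
#' @param heterogeneity Between-participant coefficient of variation applied
#'   multiplicatively to every behavioral mean (0 makes all participants
#'   share the phase means).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(windows, n_participants = 25,
                       start = NULL, end = NULL, seed = 1L,
                       gps_period = 300, gps_missingness = 0.1,
                       gps_jitter_m = 10, obfuscation = TRUE,
                       hr_period = 60, hr_sample_sd = 3, epoch_len = 30,
                       heterogeneity = 0.15) {
  stopifnot(n_participants >= 1, gps_period > 0, epoch_len > 0,
            gps_missingness >= 0, gps_missingness < 1, heterogeneity >= 0)
  all_dates <- c(windows$baseline, windows$prelockdown, windows$lockdown)
  if (is.null(start)) start <- min(all_dates)
  if (is.null(end)) end <- max(all_dates)
  start <- as.Date(start); end <- as.Date(end)
  if (start > min(all_dates) || end < max(all_dates)) {
    stop("date range [", start, ", ", end,
         "] does not span the phase windows", call. = FALSE)
  }
  structure(list(windows = windows, n_participants = n_participants,
                 start = start, end = end, seed = as.integer(seed),
                 gps_period = gps_period, gps_missingness = gps_missingness,
                 gps_jitter_m = gps_jitter_m, obfuscation = obfuscation,
                 hr_period = hr_period, hr_sample_sd = hr_sample_sd,
                 epoch_len = epoch_len, heterogeneity = heterogeneity),
            class = "sim_config")
}

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Participant-level random effects: one multiplicative lognormal factor per
# behavioral mean, shared across phases (so a null configuration stays null).
.draw_profile <- function(params, heterogeneity) {
  mean_cols <- c("homestay_h_mean", "excursion_logkm_mean", "n_trips",
                 "bt_rate", "steps_mean", "hr_mean", "sleep_h_mean",
                 "bedtime_min_mean", "unlock_h_mean", "social_h_mean")
  fac <- stats::setNames(exp(stats::rnorm(length(mean_cols), 0,
                                          heterogeneity)), mean_cols)
  out <- params
  for (cc in mean_cols) {
    if (cc == "excursion_logkm_mean") {
      out[[cc]] <- out[[cc]] + log(fac[[cc]]) # multiplicative on the km scale
    } else if (cc == "hr_mean") {
      # heart rate varies far less than 15% between people; damp the effect
      out[[cc]] <- out[[cc]] * fac[[cc]]^0.15
    } else {
      out[[cc]] <- out[[cc]] * fac[[cc]]
    }
  }
  out
}

#' Synthetic participant metadata
#'
#' @param n Number of participants.
#' @param cohort Cohort label.
#' @return Metadata tibble (`pid`, `age`, `gender`, `bmi`, `degree`,
#'   `cohort`) drawn from plausible marginal distributions.
#' @export
simulate_metadata <- function(n, cohort = "SYN") {
  tibble::tibble(
    pid = sprintf("P%03d", seq_len(n)),
    age = round(stats::runif(n, 18, 75)),
    gender = sample(c("male", "female", "other"), n, replace = TRUE,
                    prob = c(0.49, 0.49, 0.02)),
    bmi = round(.clamp(stats::rnorm(n, 26, 4), 16, 45), 1),
    degree = stats::runif(n) < 0.5,
    cohort = cohort
  )
}

# Daily behavioral targets (ground truth) for one participant. `profile` is
# a behavior_params tibble with participant effects applied.
.draw_daily_targets <- function(pid, profile, dates, phases, cfg) {
  n <- length(dates)
  idx <- match(phases, profile$phase)
  idx[is.na(idx)] <- match("baseline", profile$phase) # outside-phase days
  pr <- profile[idx, ]
  grid_min <- cfg$gps_period / 60
  homestay_h <- .clamp(stats::rnorm(n, pr$homestay_h_mean, pr$homestay_h_sd),
                       0, 15)
  homestay_min <- 900 - grid_min *
    round((900 - homestay_h * 60) / grid_min)
  away_min <- 900 - homestay_min
  n_trips <- ifelse(away_min < 2 * grid_min, 0L,
                    pmin(pmax(1L, stats::rpois(n, pr$n_trips)),
                         floor(away_min / (2 * grid_min))))
  homestay_min[n_trips == 0L] <- 900
  excursion_km <- .clamp(exp(stats::rnorm(n, pr$excursion_logkm_mean,
                                          pr$excursion_logkm_sd)), 0.3, 40)
  excursion_km[n_trips == 0L] <- 0
  bedtime_min <- round(.clamp(stats::rnorm(n, pr$bedtime_min_mean,
                                           pr$bedtime_min_sd), 0, 420) * 2) / 2
  sleep_min <- round(.clamp(stats::rnorm(n, pr$sleep_h_mean * 60,
                                         pr$sleep_h_sd * 60),
                            180, 900 - bedtime_min) * 2) / 2
  tibble::tibble(
    pid = pid, date = dates, phase = phases,
    homestay_min = homestay_min,
    n_trips = n_trips,
    max_dist_km = excursion_km,
    bt_rate = pmax(0.2, pr$bt_rate),
    steps = as.integer(round(.clamp(stats::rnorm(n, pr$steps_mean,
                                                 pr$steps_sd), 0, 40000))),
    hr_mean = .clamp(stats::rnorm(n, pr$hr_mean, pr$hr_sd), 40, 140),
    sleep_min = sleep_min,
    bedtime_min = bedtime_min,
    unlock_min = .clamp(stats::rnorm(n, pr$unlock_h_mean * 60,
                                     pr$unlock_h_sd * 60), 5, 960),
    social_min = .clamp(stats::rnorm(n, pr$social_h_mean * 60,
                                     pr$social_h_sd * 60), 0, 480)
  )
}

#' Simulate daily feature values for a cohort without sensor streams
#'
#' Draws every participant's daily behavioral targets -- the same draws that
#' drive the stream generator -- and reports them directly as a
#' participant-day feature table. This is the fast path for Monte-Carlo
#' studies of the phase statistics (the stream materialisation and
#' extraction layers add only discretisation error around these values).
#'
#' @param cfg A [sim_config()].
#' @param params A [behavior_params()] table.
#' @param shift Optional subgroup effect: a list with elements `feature`
#'   (feature column name), `selector` (function of the metadata tibble
#'   returning a logical vector), `amount` (added, in the feature's unit),
#'   and optionally `phase` (restrict the shift to one phase).
#' @return List with `features` (tibble: `pid`, `date`, `phase`, nine
#'   feature columns) and `metadata`.
#' @export
simulate_feature_table <- function(cfg, params = behavior_params(),
                                   shift = NULL) {
  set.seed(cfg$seed)
  dates <- seq(cfg$start, cfg$end, by = "day")
  phases <- phase_of(dates, cfg$windows)
  metadata <- simulate_metadata(cfg$n_participants)
  feats <- purrr::map(seq_len(cfg$n_participants), function(i) {
    profile <- .draw_profile(params, cfg$heterogeneity)
    tg <- .draw_daily_targets(metadata$pid[i], profile, dates, phases, cfg)
    tg$max_nearby <- as.integer(apply(
      matrix(stats::rpois(24 * nrow(tg), rep(tg$bt_rate, each = 24)),
             nrow = 24), 2, max))
    tg$max_dist_m <- tg$max_dist_km * 1000
    tg[c("pid", "date", "phase", "homestay_min", "max_dist_m", "max_nearby",
         "steps", "hr_mean", "sleep_min", "bedtime_min", "unlock_min",
         "social_min")]
  }) |> dplyr::bind_rows()
  if (!is.null(shift)) {
    sel <- metadata$pid[shift$selector(metadata)]
    rows <- feats$pid %in% sel
    if (!is.null(shift$phase)) rows <- rows & feats$phase == shift$phase
    feats[[shift$feature]][rows] <- feats[[shift$feature]][rows] + shift$amount
  }
  list(features = feats, metadata = metadata)
}

# ---- stream materialisation -------------------------------------------------

.deg_per_m_lat <- 1 / 111194.9265 # one meter in degrees of latitude

# GPS fixes for one participant-day on the fix grid, plus realised maximum
# distance bookkeeping. Returns list(fixes, max_dist_m).
.gen_gps_day <- function(date, target, home, cfg) {
  period <- cfg$gps_period
  secs <- seq(0, 86400 - period, by = period)
  n <- length(secs)
  r <- numeric(n) # radial distance from home, meters
  if (target$n_trips > 0L) {
    grid_min <- period / 60
    slots0 <- 8 * 3600 / period # first stay-window interval index
    n_slots <- (23 - 8) * 3600 / period
    k_away <- as.integer(round((900 - target$homestay_min) / grid_min))
    m <- target$n_trips
    # trip lengths in intervals, each >= 2, summing to k_away
    lens <- rep(2L, m)
    extra <- k_away - 2L * m
    if (extra > 0L) {
      add <- stats::rmultinom(1, extra, rep(1, m))[, 1]
      lens <- lens + add
    }
    gaps <- stats::rmultinom(1, n_slots - k_away, rep(1, m + 1))[, 1]
    starts <- slots0 + cumsum(gaps)[seq_len(m)] +
      c(0L, cumsum(lens))[seq_len(m)]
    d_max <- target$max_dist_km * 1000
    dists <- c(d_max, d_max * stats::runif(m - 1, 0.3, 0.9))
    ord <- sample.int(m)
    dists <- dists[order(ord)] # longest trip in random position
    r_min <- 250 # beyond the 200 m homestay radius
    for (j in seq_len(m)) {
      l <- lens[j]
      jj <- seq_len(l - 1L)
      w <- pmin(1, pmin(jj, l - jj) / floor(l / 2))
      r[starts[j] + jj + 1L] <- pmax(r_min, max(dists[j], r_min + 10) * w)
    }
  }
  theta <- stats::runif(1, 0, 2 * pi)
  lat <- home$lat + r * cos(theta) * .deg_per_m_lat
  lon <- home$lon + r * sin(theta) * .deg_per_m_lat / cos(home$lat * pi / 180)
  if (cfg$gps_jitter_m > 0) {
    lat <- lat + stats::rnorm(n, 0, cfg$gps_jitter_m) * .deg_per_m_lat
    lon <- lon + stats::rnorm(n, 0, cfg$gps_jitter_m) * .deg_per_m_lat
  }
  t <- .day_time(date, 0) + secs
  in_stay <- secs >= 8 * 3600 & secs <= 23 * 3600
  max_dist <- max(haversine_m(lat[in_stay], lon[in_stay], home$lat, home$lon))
  fixes <- tibble::tibble(t = t, lat = lat, lon = lon)
  if (cfg$gps_missingness > 0) {
    fixes <- fixes[stats::runif(n) >= cfg$gps_missingness, , drop = FALSE]
  }
  list(fixes = fixes, max_dist_m = max_dist)
}

.stage_probs <- c(light = 0.55, deep = 0.25, rem = 0.20)

# Sleep epochs for one night: optional wake run, then the sleep block.
.gen_sleep_day <- function(date, target, cfg) {
  el <- cfg$epoch_len
  n_sleep <- as.integer(round(target$sleep_min * 60 / el))
  n_wake <- min(stats::rpois(1, 4),
                as.integer(floor(target$bedtime_min * 60 / el)))
  bed <- .day_time(date, 20) + target$bedtime_min * 60
  starts <- bed + seq(-n_wake, n_sleep - 1L) * el
  stage <- c(rep("wake", n_wake),
             sample(names(.stage_probs), n_sleep, replace = TRUE,
                    prob = .stage_probs))
  tibble::tibble(t = starts, stage = stage, epoch_len = el)
}

# Non-overlapping unlock/standby sessions within 06:30-23:30 of `date`.
# Session bounds are integer seconds so the replayed total is exact.
.gen_phone_day <- function(date, target, cfg) {
  total <- min(target$unlock_min, 960)
  m <- 1L + stats::rpois(1, 6)
  w <- stats::rexp(m)
  dur_s <- pmax(10, round(.clamp(total * w / sum(w), 0.2, 200) * 60))
  free_s <- 17 * 3600 - sum(dur_s)
  gw <- stats::runif(m + 1)
  gaps_s <- pmax(1, floor(free_s * gw / sum(gw)))
  start_s <- 6.5 * 3600 + cumsum(gaps_s)[seq_len(m)] +
    c(0, cumsum(dur_s))[seq_len(m)]
  t0 <- .day_time(date, 0)
  ev <- tibble::tibble(
    t = t0 + c(rbind(start_s, start_s + dur_s)),
    state = rep(c("unlock", "standby"), m))
  list(events = ev, unlock_min = sum(dur_s) / 60)
}

.app_other <- c("Tools", "Games", "Productivity", "Health & Fitness", "News")

.gen_app_day <- function(date, target, cfg) {
  ms <- 1L + stats::rpois(1, 5)
  w <- stats::rexp(ms)
  sdur <- round(target$social_min * 60 * w / sum(w), 1) # seconds
  mo <- stats::rpois(1, 8)
  odur <- round(stats::rexp(mo, 1 / 600), 1)
  t0 <- .day_time(date, 0)
  tt <- t0 + round(stats::runif(ms + mo, 7 * 3600, 23 * 3600))
  ev <- tibble::tibble(
    t = tt,
    duration = c(sdur, odur),
    category = c(sample(c("Social", "Communication", "Dating"), ms,
                        replace = TRUE),
                 if (mo > 0) sample(.app_other, mo, replace = TRUE))) |>
    dplyr::arrange(.data$t)
  list(events = ev, social_min = sum(sdur) / 60)
}

#' Simulate one participant's sensor streams
#'
#' Materialises all seven streams from the participant's daily behavioral
#' targets and returns them with the realised ground truth. The GPS trace
#' alternates home dwell and out-and-back excursions aligned to the fix
#' grid; sleep epochs form a contiguous block starting at the drawn bedtime;
#' unlock/standby events alternate; app events carry social and non-social
#' categories.
#'
#' @param pid Participant identifier.
#' @param targets Daily target tibble for this participant (one row per
#'   date, as produced by the internal draw layer).
#' @param cfg A [sim_config()].
#' @return List with `streams` (named list of the seven stream tibbles) and
#'   `truth` (tibble: `pid`, `date`, `phase`, nine realised feature values).
#' @export
simulate_participant <- function(pid, targets, cfg) {
  home <- list(lat = stats::runif(1, 36, 58), lon = stats::runif(1, -8, 18))
  obf <- if (cfg$obfuscation) {
    c(lat = stats::runif(1, -0.1, 0.1), lon = stats::runif(1, -0.5, 0.5))
  } else c(lat = 0, lon = 0)

  days <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    d <- tg$date
    gps <- .gen_gps_day(d, tg, home, cfg)
    phone <- .gen_phone_day(d, tg, cfg)
    hr_t <- .day_time(d, 6) + seq(0, 86400 - cfg$hr_period, by = cfg$hr_period)
    hr_v <- .clamp(tg$hr_mean + stats::rnorm(length(hr_t), 0,
                                             cfg$hr_sample_sd), 30, 220)
    bt_t <- .day_time(d, 6) + seq(1800, 86400 - 1800, by = 3600)
    bt_v <- stats::rpois(length(bt_t), tg$bt_rate)
    sleep <- .gen_sleep_day(d, tg, cfg)
    app <- .gen_app_day(d, tg, cfg)
    list(
      gps = gps$fixes,
      app = app$events,
      bluetooth = tibble::tibble(t = bt_t, n_nearby = as.integer(bt_v)),
      steps = tibble::tibble(t = .day_time(d, 20), steps = tg$steps),
      heart_rate = tibble::tibble(t = hr_t, bpm = hr_v),
      sleep = sleep,
      phone = phone$events,
      truth = tibble::tibble(
        pid = pid, date = d, phase = tg$phase,
        homestay_min = tg$homestay_min,
        max_dist_m = gps$max_dist_m,
        max_nearby = as.integer(max(bt_v)),
        steps = tg$steps,
        hr_mean = mean(hr_v),
        sleep_min = tg$sleep_min,
        bedtime_min = tg$bedtime_min,
        unlock_min = phone$unlock_min,
        social_min = app$social_min)
    )
  })
  streams <- lapply(stats::setNames(nm = modalities()), function(m) {
    dplyr::bind_rows(lapply(days, `[[`, m))
  })
  streams$gps$lat <- streams$gps$lat + obf[["lat"]]
  streams$gps$lon <- streams$gps$lon + obf[["lon"]]
  truth <- dplyr::bind_rows(lapply(days, `[[`, "truth"))
  list(streams = streams, truth = truth)
}

#' Simulate and write a full synthetic cohort dataset
#'
#' Generates `cfg$n_participants` participants (with participant-level
#' random effects on every behavioral mean), materialises their sensor
#' streams, and writes the standard dataset layout: one
#' `<pid>.<modality>.csv` per stream, `metadata.csv`, and
#' `ground_truth.csv` holding the generator's realised daily feature values.
#'
#' @param cfg A [sim_config()].
#' @param params A [behavior_params()] table.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; side effect: the dataset files.
#' @export
simulate_cohort <- function(cfg, params = behavior_params(),
                            dir = tempfile("cohort")) {
  set.seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dates <- seq(cfg$start, cfg$end, by = "day")
  phases <- phase_of(dates, cfg$windows)
  metadata <- simulate_metadata(cfg$n_participants)
  truths <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    profile <- .draw_profile(params, cfg$heterogeneity)
    targets <- .draw_daily_targets(metadata$pid[i], profile, dates, phases,
                                   cfg)
    sim <- simulate_participant(metadata$pid[i], targets, cfg)
    for (m in modalities()) {
      write_stream(sim$streams[[m]], stream_path(dir, metadata$pid[i], m), m)
    }
    truths[[i]] <- sim$truth
  }
  write_metadata(metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(dplyr::bind_rows(truths),
                   file.path(dir, "ground_truth.csv"), progress = FALSE)
  invisible(dir)
}

#' Read the ground-truth table written by [simulate_cohort()]
#'
#' @param dir Dataset directory.
#' @return Tibble of realised daily feature values per participant.
#' @export
read_ground_truth <- function(dir) {
  readr::read_csv(file.path(dir, "ground_truth.csv"),
                  col_types = readr::cols(pid = "c", date = "D", phase = "c",
                                          .default = "d"),
                  progress = FALSE)
}
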