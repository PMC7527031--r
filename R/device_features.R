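# Daily wearable and Bluetooth features. All features use the 6 AM-6 AM
# feature day except the sleep features, which use an 8 PM-11 AM window and
# are attributed to the day the window starts.

# Calendar day owning the 6 AM-6 AM feature day containing t
.feature_day <- function(t) {
  as.Date(as.numeric(t) %/% 86400 - (as.numeric(t) %% 86400 < 6 * 3600),
          origin = "1970-01-01")
}

# Day whose 8 PM-11 AM sleep window contains epoch start t (NA outside)
.sleep_day <- function(t) {
  secs <- as.numeric(t) %% 86400
  day <- as.Date(as.numeric(t) %/% 86400, origin = "1970-01-01")
  out <- rep(as.Date(NA), length(t))
  out[secs >= 20 * 3600] <- day[secs >= 20 * 3600]
  out[secs < 11 * 3600] <- day[secs < 11 * 3600] - 1L
  out
}

.in_feature_day <- function(t, date) {
  start <- .day_time(date, 6)
  t >= start & t < start + 86400
}

#' Daily maximum number of nearby Bluetooth devices
#'
#' @param scans Tibble of Bluetooth scans (`t`, `n_nearby`).
#' @param date Feature day (6 AM of `date` to 6 AM of the next day).
#' @return Integer maximum, or `NA` when the day has no scans.
#' @export
daily_max_nearby <- function(scans, date) {
  x <- scans$n_nearby[.in_feature_day(scans$t, date)]
  if (length(x) == 0L) return(NA_integer_)
  as.integer(max(x))
}

#' Daily total step count
#'
#' @param records Tibble of step records (`t`, `steps`).
#' @param date Feature day.
#' @return Integer total, or `NA` when the day has no records.
#' @export
daily_steps <- function(records, date) {
  x <- records$steps[.in_feature_day(records$t, date)]
  if (length(x) == 0L) return(NA_integer_)
  as.integer(sum(x))
}

#' Daily mean heart rate
#'
#' Arithmetic mean of the wearable's heart-rate readings over the feature
#' day; no minimum wear time is imposed (a day with any reading gets a
#' value).
#'
#' @param samples Tibble of heart-rate samples (`t`, `bpm`).
#' @param date Feature day.
#' @return Mean bpm, or `NA` when the day has no samples.
#' @export
daily_mean_hr <- function(samples, date) {
  x <- samples$bpm[.in_feature_day(samples$t, date)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

.is_sleep_stage <- function(stage) stage %in% c("light", "deep", "rem")

.sleep_window_epochs <- function(epochs, date) {
  w0 <- .day_time(date, 20)
  w1 <- .day_time(date, 35) # 11 AM next day
  epochs[epochs$t >= w0 & epochs$t < w1, , drop = FALSE]
}

#' Daily sleep duration in minutes
#'
#' Total time in the three sleep stages (light, deep, REM) over the 8 PM to
#' 11 AM window, counting each epoch whose start lies in the window; wake
#' epochs are excluded.
#'
#' @param epochs Tibble of sleep epochs (`t`, `stage`, `epoch_len`).
#' @param date Day on which the sleep window starts.
#' @return Minutes asleep (0 when the window holds only wake epochs), or
#'   `NA` when the window has no epochs at all.
#' @export
sleep_duration <- function(epochs, date) {
  win <- .sleep_window_epochs(epochs, date)
  if (nrow(win) == 0L) return(NA_real_)
  sum(win$epoch_len[.is_sleep_stage(win$stage)]) / 60
}

#' Bedtime in minutes after 8 PM
#'
#' Start time of the first sleep-stage (non-wake) epoch in the 8 PM-11 AM
#' window, encoded as minutes elapsed since 8 PM so that the scale is
#' monotone across midnight (11:10 PM is 190; 1 AM is 300).
#'
#' @inheritParams sleep_duration
#' @return Minutes after 8 PM, or `NA` when the window has no sleep-stage
#'   epoch.
#' @export
bedtime <- function(epochs, date) {
  win <- .sleep_window_epochs(epochs, date)
  asleep <- win$t[.is_sleep_stage(win$stage)]
  if (length(asleep) == 0L) return(NA_real_)
  as.numeric(min(asleep) - .day_time(date, 20), units = "mins")
}

#' Daily wearable and Bluetooth features for one participant
#'
#' Vectorised driver over a multi-day stream set: every record is assigned
#' to exactly one feature day, then per-day summaries are computed.
#'
#' @param streams Named list with any of `bluetooth`, `steps`, `heart_rate`,
#'   `sleep` tibbles (missing entries simply yield `NA` columns).
#' @param dates Feature days to report.
#' @return Tibble with columns `date`, `max_nearby`, `steps`, `hr_mean`,
#'   `sleep_min`, `bedtime_min`.
#' @export
device_features <- function(streams, dates) {
  out <- tibble::tibble(date = as.Date(dates))
  join <- function(out, tab) dplyr::left_join(out, tab, by = "date")

  if (!is.null(streams$bluetooth) && nrow(streams$bluetooth) > 0L) {
    bt <- streams$bluetooth |>
      dplyr::mutate(date = .feature_day(.data$t)) |>
      dplyr::summarise(max_nearby = as.integer(max(.data$n_nearby)),
                       .by = "date")
    out <- join(out, bt)
  } else out$max_nearby <- NA_integer_

  if (!is.null(streams$steps) && nrow(streams$steps) > 0L) {
    st <- streams$steps |>
      dplyr::mutate(date = .feature_day(.data$t)) |>
      dplyr::summarise(steps = as.integer(sum(.data$steps)), .by = "date")
    out <- join(out, st)
  } else out$steps <- NA_integer_

  if (!is.null(streams$heart_rate) && nrow(streams$heart_rate) > 0L) {
    hr <- streams$heart_rate |>
      dplyr::mutate(date = .feature_day(.data$t)) |>
      dplyr::summarise(hr_mean = mean(.data$bpm), .by = "date")
    out <- join(out, hr)
  } else out$hr_mean <- NA_real_

  if (!is.null(streams$sleep) && nrow(streams$sleep) > 0L) {
    sl <- streams$sleep |>
      dplyr::mutate(date = .sleep_day(.data$t)) |>
      dplyr::filter(!is.na(.data$date)) |>
      dplyr::summarise(
        sleep_min = sum(.data$epoch_len[.is_sleep_stage(.data$stage)]) / 60,
        bedtime_min = {
          asleep <- .data$t[.is_sleep_stage(.data$stage)]
          if (length(asleep) == 0L) NA_real_ else
            as.numeric(min(asleep) - .day_time(.data$date[1L], 20),
                       units = "mins")
        },
        .by = "date")
    out <- join(out, sl)
  } else {
    out$sleep_min <- NA_real_
    out$bedtime_min <- NA_real_
  }
  out
}
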