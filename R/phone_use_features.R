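# Daily phone-interaction features: unlock duration from unlock/standby
# event streams and social-app use duration from categorised app events.

#' Configuration for phone-use features
#'
#' @param max_session Seconds; unlock sessions longer than this are excluded
#'   (they usually reflect a missed standby event or a phone left unlocked).
#' @param social_categories App-store category names counted as social;
#'   matching is case insensitive.
#' @return A list of class `unlock_config`.
#' @export
unlock_config <- function(max_session = 14400,
                          social_categories = c("Social", "Communication",
                                                "Dating")) {
  stopifnot(max_session > 0, length(social_categories) > 0)
  structure(list(max_session = max_session,
                 social_categories = social_categories),
            class = "unlock_config")
}

#' Unlock sessions from a phone-state event stream
#'
#' Replays the unlock/standby stream: each session starts at an unlock event
#' and ends at the next standby. Repeated unlocks before a standby keep the
#' first; standby events with no open session and a trailing unmatched
#' unlock are ignored.
#'
#' @param events Tibble of phone events (`t`, `state`), time sorted.
#' @return Tibble with columns `start`, `end`, `duration` (seconds).
#' @export
unlock_sessions <- function(events) {
  empty <- tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration = numeric())
  n <- nrow(events)
  if (n == 0L) return(empty)
  u <- events$state == "unlock"
  # first unlock of each unlock-run opens a session
  opens <- which(u & !c(FALSE, u[-n]))
  closes <- which(!u)
  if (length(opens) == 0L || length(closes) == 0L) return(empty)
  nxt <- closes[findInterval(opens, closes) + 1L]
  keep <- !is.na(nxt)
  start <- events$t[opens[keep]]
  end <- events$t[nxt[keep]]
  tibble::tibble(start = start, end = end,
                 duration = as.numeric(end) - as.numeric(start))
}

#' Daily phone unlock duration in minutes
#'
#' Sums the unlock sessions whose unlock event falls in the 6 AM-6 AM
#' feature day, excluding single sessions longer than `max_session` (4 hours
#' by default). A session spanning the 6 AM boundary is attributed to the
#' day of its unlock event.
#'
#' @param events Tibble of phone events (`t`, `state`), time sorted.
#' @param date Feature day.
#' @param cfg An [unlock_config()].
#' @return Minutes unlocked.
#' @export
unlock_duration <- function(events, date, cfg = unlock_config()) {
  s <- unlock_sessions(events)
  s <- s[.in_feature_day(s$start, date) & s$duration <= cfg$max_session, ,
         drop = FALSE]
  sum(s$duration) / 60
}

#' Daily social-app use duration in minutes
#'
#' Sums app-event durations over the feature day for events whose category
#' is one of the configured social categories (app-store categories Social,
#' Communication and Dating by default, compared case-insensitively). All
#' other categories count as non-social.
#'
#' @param events Tibble of app events (`t`, `duration`, `category`).
#' @param date Feature day.
#' @param cfg An [unlock_config()].
#' @return Minutes of social-app use.
#' @export
social_app_duration <- function(events, date, cfg = unlock_config()) {
  day <- events[.in_feature_day(events$t, date), , drop = FALSE]
  social <- tolower(day$category) %in% tolower(cfg$social_categories)
  sum(day$duration[social]) / 60
}

#' Daily phone-use features for one participant
#'
#' @param streams Named list with any of `phone`, `app` tibbles.
#' @param dates Feature days to report.
#' @param cfg An [unlock_config()].
#' @return Tibble with columns `date`, `unlock_min`, `social_min`; a day
#'   with no events for a modality gets `NA` for that modality's feature.
#' @export
phone_use_features <- function(streams, dates, cfg = unlock_config()) {
  out <- tibble::tibble(date = as.Date(dates))

  if (!is.null(streams$phone) && nrow(streams$phone) > 0L) {
    s <- unlock_sessions(streams$phone)
    s <- s[s$duration <= cfg$max_session, , drop = FALSE]
    sums <- tibble::tibble(date = .feature_day(s$start), mins = s$duration / 60) |>
      dplyr::summarise(unlock_min = sum(.data$mins), .by = "date")
    present <- unique(.feature_day(streams$phone$t))
    out <- dplyr::left_join(out, sums, by = "date")
    out$unlock_min[is.na(out$unlock_min) & out$date %in% present] <- 0
  } else out$unlock_min <- NA_real_

  if (!is.null(streams$app) && nrow(streams$app) > 0L) {
    ap <- streams$app |>
      dplyr::mutate(date = .feature_day(.data$t)) |>
      dplyr::summarise(
        social_min = sum(.data$duration[
          tolower(.data$category) %in% tolower(cfg$social_categories)]) / 60,
        .by = "date")
    out <- dplyr::left_join(out, ap, by = "date")
  } else out$social_min <- NA_real_
  out
}
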