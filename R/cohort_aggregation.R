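# Cohort-level assembly: per-participant daily feature extraction across all
# modalities, and daily cross-participant median/quartile series under the
# minimum-participant rule.

#' Names of the nine daily behavioral features
#'
#' @return Character vector: `homestay_min`, `max_dist_m`, `max_nearby`,
#'   `steps`, `hr_mean`, `sleep_min`, `bedtime_min`, `unlock_min`,
#'   `social_min`.
#' @export
feature_names <- function() {
  c("homestay_min", "max_dist_m", "max_nearby", "steps", "hr_mean",
    "sleep_min", "bedtime_min", "unlock_min", "social_min")
}

#' Extract one participant's daily features from their streams
#'
#' @param streams Named list of stream tibbles (any subset of
#'   [modalities()]).
#' @param dates Feature days to report; defaults to the calendar span of the
#'   streams.
#' @param loc_cfg A [location_config()].
#' @param phone_cfg An [unlock_config()].
#' @return Tibble, one row per date, with the nine feature columns (`NA`
#'   where the modality had no data).
#' @export
participant_features <- function(streams, dates = NULL,
                                 loc_cfg = location_config(),
                                 phone_cfg = unlock_config()) {
  if (is.null(dates)) {
    ts <- unlist(lapply(streams, function(s) as.numeric(range(s$t))),
                 use.names = FALSE)
    if (length(ts) == 0L) stop("no stream data for participant", call. = FALSE)
    rng <- range(.feature_day(as.POSIXct(ts, origin = "1970-01-01",
                                         tz = "UTC")))
    dates <- seq(rng[1], rng[2], by = "day")
  }
  loc <- if (!is.null(streams$gps) && nrow(streams$gps) > 0L) {
    location_features(streams$gps, dates, loc_cfg)
  } else {
    tibble::tibble(date = as.Date(dates), homestay_min = NA_real_,
                   max_dist_m = NA_real_)
  }
  dev <- device_features(streams, dates)
  ph <- phone_use_features(streams, dates, phone_cfg)
  loc |>
    dplyr::left_join(dev, by = "date") |>
    dplyr::left_join(ph, by = "date")
}

#' Build the participant-day feature table for a dataset directory
#'
#' Reads every participant's stream files (`<pid>.<modality>.csv`), extracts
#' the nine daily features, and outer-joins them into one row per
#' participant per day. Participants are taken from `metadata.csv` when
#' present, otherwise inferred from the file names.
#'
#' @param dir Dataset directory.
#' @param loc_cfg A [location_config()].
#' @param phone_cfg An [unlock_config()].
#' @return Tibble with `pid`, `date` and the nine feature columns.
#' @export
build_feature_table <- function(dir, loc_cfg = location_config(),
                                phone_cfg = unlock_config()) {
  meta_path <- file.path(dir, "metadata.csv")
  pids <- if (file.exists(meta_path)) {
    read_metadata(meta_path)$pid
  } else {
    unique(sub("\\.[^.]+\\.csv$", "",
               basename(list.files(dir, pattern = "\\.csv$"))))
  }
  pids <- setdiff(pids, c("metadata", "ground_truth"))
  rows <- lapply(pids, function(pid) {
    streams <- list()
    for (m in modalities()) {
      p <- stream_path(dir, pid, m)
      if (file.exists(p)) streams[[m]] <- read_stream(p, m)
    }
    if (length(streams) == 0L) return(NULL)
    dplyr::mutate(participant_features(streams, loc_cfg = loc_cfg,
                                       phone_cfg = phone_cfg),
                  pid = pid, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out[c("pid", "date")]) > 0L) {
    stop("duplicate pid/date rows in feature table", call. = FALSE)
  }
  # a participant-day exists only when some modality contributed that day
  keep <- rowSums(!is.na(out[feature_names()])) > 0L
  out[keep, , drop = FALSE]
}

#' Cross-participant percentiles of one feature on one day
#'
#' Linear-interpolation percentiles (quantile type 7) over the participants
#' with a present value that day; all three percentiles are `NA` when fewer
#' than `min_n` participants contribute.
#'
#' @param table Participant-day feature table.
#' @param feature Feature column name.
#' @param date Calendar day.
#' @param min_n Minimum number of contributing participants (20, matching
#'   the cohort analysis prerequisite).
#' @return One-row tibble: `median`, `q25`, `q75`, `n`.
#' @export
cohort_percentiles <- function(table, feature, date, min_n = 20) {
  x <- table[[feature]][table$date == as.Date(date)]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n) {
    return(tibble::tibble(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                          n = n))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = n)
}

#' Daily cohort median/quartile series for every feature
#'
#' @param table Participant-day feature table.
#' @param features Feature columns to summarise.
#' @param min_n Minimum participants per feature per day; days below the
#'   minimum get `NA` percentiles (the day is kept so gaps are visible).
#' @return Long tibble: `date`, `feature`, `median`, `q25`, `q75`, `n`.
#' @export
cohort_daily <- function(table, features = feature_names(), min_n = 20) {
  table |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(
      median = stats::quantile(.data$value, 0.5, type = 7, names = FALSE),
      q25 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
      n = dplyr::n(),
      .by = c("date", "feature")) |>
    dplyr::mutate(dplyr::across(c("median", "q25", "q75"),
                                ~ ifelse(.data$n < min_n, NA_real_, .x))) |>
    dplyr::arrange(.data$feature, .data$date)
}

#' Plot a cohort daily series with optional event markers
#'
#' Median line with an interquartile ribbon, optionally annotated with
#' vertical lines at supplied event dates (for example lockdown
#' announcements).
#'
#' @param series Output of [cohort_daily()].
#' @param feature Feature to plot.
#' @param events Optional named vector of dates.
#' @return A ggplot object.
#' @export
plot_cohort_series <- function(series, feature, events = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cohort_series() needs the ggplot2 package", call. = FALSE)
  }
  dat <- series[series$feature == feature, ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    p <- p + ggplot2::geom_vline(xintercept = as.Date(events),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
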