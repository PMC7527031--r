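# GPS pipeline: spurious-fix filtering, nightly home-location inference by
# density-based clustering, daily homestay, and daily maximum distance from
# home. Distances are meters on a sphere of radius 6,371,000 m; homestay is
# reported in minutes.

#' Configuration for the GPS feature pipeline
#'
#' @param spurious_deg Degrees: a fix differing from both its neighbours by
#'   more than this (in latitude or longitude) is removed as spurious.
#' @param home_radius_m Meters: a fix within this radius of home counts as
#'   at home.
#' @param max_gap Seconds: inter-fix gaps longer than this are excluded from
#'   homestay (guards against counting large data gaps as time at home).
#' @param home_window Numeric length-2, hours since midnight of the night's
#'   start day: window used for home-location clustering. The default
#'   `c(20, 28)` is 8 PM to 4 AM the next day.
#' @param stay_window Numeric length-2, hours since midnight: window over
#'   which homestay and maximum distance are computed (8 AM to 11 PM).
#' @param cluster_eps_m DBSCAN neighbourhood radius, meters.
#' @param cluster_min_pts DBSCAN core-point threshold (neighbourhood includes
#'   the point itself).
#' @return A list of class `location_config`.
#' @export
location_config <- function(spurious_deg = 5, home_radius_m = 200,
                            max_gap = 3600, home_window = c(20, 28),
                            stay_window = c(8, 23),
                            cluster_eps_m = 100, cluster_min_pts = 3) {
  stopifnot(spurious_deg > 0, home_radius_m > 0, max_gap > 0,
            cluster_eps_m > 0, cluster_min_pts >= 1,
            length(home_window) == 2, length(stay_window) == 2,
            stay_window[1] < stay_window[2],
            stay_window[1] >= 0, stay_window[2] <= 24)
  structure(list(spurious_deg = spurious_deg, home_radius_m = home_radius_m,
                 max_gap = max_gap, home_window = home_window,
                 stay_window = stay_window, cluster_eps_m = cluster_eps_m,
                 cluster_min_pts = cluster_min_pts),
            class = "location_config")
}

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance(s) in meters.
#' @export
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of equatorial arc, ~111.19 km
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371000
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# POSIXct for `hours` (possibly > 24) after local midnight of `date`
.day_time <- function(date, hours) {
  as.POSIXct(as.numeric(as.POSIXct(paste0(as.character(date), " 00:00:00"),
                                   tz = "UTC")) + hours * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Remove spurious GPS fixes
#'
#' A fix is removed when it differs from the preceding fix by more than
#' `spurious_deg` degrees (in latitude or in longitude) and likewise from the
#' following fix. Comparisons use the original neighbours (single pass); the
#' first and last fixes are never removed.
#'
#' @param fixes Tibble of GPS fixes (`t`, `lat`, `lon`), time sorted.
#' @param cfg A [location_config()].
#' @return The fixes with spurious rows dropped.
#' @export
filter_spurious <- function(fixes, cfg = location_config()) {
  n <- nrow(fixes)
  if (n < 3L) return(fixes)
  s <- cfg$spurious_deg
  lat <- fixes$lat
  lon <- fixes$lon
  i <- 2:(n - 1L)
  from_prev <- abs(lat[i] - lat[i - 1L]) > s | abs(lon[i] - lon[i - 1L]) > s
  from_next <- abs(lat[i] - lat[i + 1L]) > s | abs(lon[i] - lon[i + 1L]) > s
  drop <- c(FALSE, from_prev & from_next, FALSE)
  fixes[!drop, , drop = FALSE]
}

# Plain DBSCAN over a precomputed distance matrix. Returns integer labels,
# 0 = noise. Neighbourhoods include the point itself.
.dbscan_labels <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n) # 0 = noise/unvisited
  visited <- logical(n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (visited[p] || !core[p]) next
    cl <- cl + 1L
    queue <- p
    visited[p] <- TRUE
    labels[p] <- cl
    while (length(queue) > 0L) {
      q <- queue[1L]
      queue <- queue[-1L]
      for (r in nbrs[[q]]) {
        if (labels[r] == 0L) labels[r] <- cl
        if (!visited[r] && core[r]) {
          visited[r] <- TRUE
          queue <- c(queue, r)
        }
      }
    }
  }
  labels
}

#' Infer the nightly home location
#'
#' Clusters the fixes observed between 8 PM of `date` and 4 AM of the next
#' day with DBSCAN (haversine metric) and returns the mean coordinate of the
#' cluster containing the *last* fix of the night. The largest nightly
#' cluster is not necessarily home (an evening out can dominate), but the
#' last position before phones go quiet usually is.
#'
#' @param fixes Tibble of (filtered) GPS fixes.
#' @param date The calendar day on which the night starts.
#' @param cfg A [location_config()].
#' @return A one-row tibble (`date`, `lat`, `lon`, `n_cluster_pts`), or
#'   `NULL` when there are no fixes in the window or the last fix is a noise
#'   point.
#' @export
infer_home <- function(fixes, date, cfg = location_config()) {
  w0 <- .day_time(date, cfg$home_window[1])
  w1 <- .day_time(date, cfg$home_window[2])
  night <- fixes[fixes$t >= w0 & fixes$t < w1, , drop = FALSE]
  n <- nrow(night)
  if (n == 0L) return(NULL)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_m(night$lat[i], night$lon[i], night$lat[j], night$lon[j])
  })
  labels <- .dbscan_labels(d, cfg$cluster_eps_m, cfg$cluster_min_pts)
  last <- labels[n]
  if (last == 0L) return(NULL)
  members <- labels == last
  tibble::tibble(date = as.Date(date),
                 lat = mean(night$lat[members]),
                 lon = mean(night$lon[members]),
                 n_cluster_pts = sum(members))
}

#' Daily homestay in minutes
#'
#' Sums, over the stay window (8 AM to 11 PM of `date`), the inter-fix
#' intervals whose two bounding fixes both lie within `home_radius_m` of the
#' home location and whose raw gap does not exceed `max_gap`. Intervals
#' straddling a window boundary are clipped to the window before summing, so
#' homestay never exceeds the window length (900 minutes).
#'
#' @param fixes Tibble of (filtered) GPS fixes for the participant.
#' @param home Home location as returned by [infer_home()] (or any list with
#'   `lat`/`lon`), or `NULL`.
#' @param date Feature day.
#' @param cfg A [location_config()].
#' @return Minutes at home, or `NA` when `home` is `NULL`.
#' @export
daily_homestay <- function(fixes, home, date, cfg = location_config()) {
  if (is.null(home)) return(NA_real_)
  w0 <- as.numeric(.day_time(date, cfg$stay_window[1]))
  w1 <- as.numeric(.day_time(date, cfg$stay_window[2]))
  tt <- as.numeric(fixes$t)
  if (!any(tt >= w0 & tt <= w1)) return(NA_real_) # no location data that day
  n <- nrow(fixes)
  if (n < 2L) return(0)
  at_home <- haversine_m(fixes$lat, fixes$lon, home$lat, home$lon) <=
    cfg$home_radius_m
  t1 <- tt[-n]
  t2 <- tt[-1L]
  ok <- at_home[-n] & at_home[-1L] & (t2 - t1) <= cfg$max_gap
  overlap <- pmax(0, pmin(t2, w1) - pmax(t1, w0))
  sum(overlap[ok]) / 60
}

#' Daily maximum distance from home in meters
#'
#' Maximum haversine distance from home over the fixes in the stay window
#' (8 AM to 11 PM); 0 when every fix in the window is exactly at home.
#'
#' @inheritParams daily_homestay
#' @return Meters, or `NA` when `home` is `NULL` or no fix falls in the
#'   window.
#' @export
daily_max_distance <- function(fixes, home, date, cfg = location_config()) {
  if (is.null(home)) return(NA_real_)
  w0 <- .day_time(date, cfg$stay_window[1])
  w1 <- .day_time(date, cfg$stay_window[2])
  day <- fixes[fixes$t >= w0 & fixes$t <= w1, , drop = FALSE]
  if (nrow(day) == 0L) return(NA_real_)
  max(haversine_m(day$lat, day$lon, home$lat, home$lon))
}

#' Daily GPS features for one participant
#'
#' Applies the spurious-fix filter once, then for each feature day infers the
#' home location from the night ending at that day's 4 AM (the night starting
#' on the previous calendar day) and computes homestay and maximum distance
#' from home over the day's 8 AM-11 PM window.
#'
#' @param fixes Tibble of raw GPS fixes for one participant.
#' @param dates Feature days to cover; defaults to every calendar day spanned
#'   by the fixes.
#' @param cfg A [location_config()].
#' @return Tibble with columns `date`, `homestay_min`, `max_dist_m` (`NA`
#'   where home could not be inferred or no fix fell in the window).
#' @export
location_features <- function(fixes, dates = NULL, cfg = location_config()) {
  fixes <- dplyr::arrange(tibble::as_tibble(fixes), .data$t)
  fixes <- filter_spurious(fixes, cfg)
  if (is.null(dates)) {
    if (nrow(fixes) == 0L) {
      return(tibble::tibble(date = as.Date(character()),
                            homestay_min = numeric(), max_dist_m = numeric()))
    }
    rng <- range(as.Date(fixes$t))
    dates <- seq(rng[1], rng[2], by = "day")
  }
  rows <- lapply(dates, function(d) {
    home <- infer_home(fixes, d - 1L, cfg)
    tibble::tibble(date = as.Date(d),
                   homestay_min = daily_homestay(fixes, home, d, cfg),
                   max_dist_m = daily_max_distance(fixes, home, d, cfg))
  })
  dplyr::bind_rows(rows)
}
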