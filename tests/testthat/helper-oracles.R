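# Brute-force reference implementations, written independently of the
# package internals: plain loops over records applying the stated rules.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Reference spurious-fix filter: explicit per-index check.
oracle_filter_spurious <- function(fixes, spurious_deg = 5) {
  n <- nrow(fixes)
  if (n < 3) return(fixes)
  keep <- rep(TRUE, n)
  for (i in 2:(n - 1)) {
    differs <- function(j) {
      abs(fixes$lat[i] - fixes$lat[j]) > spurious_deg ||
        abs(fixes$lon[i] - fixes$lon[j]) > spurious_deg
    }
    if (differs(i - 1) && differs(i + 1)) keep[i] <- FALSE
  }
  fixes[keep, ]
}

# Reference homestay: enumerate every adjacent pair, apply the radius, gap
# and window-clipping rules one pair at a time.
oracle_homestay <- function(fixes, home, date, home_radius_m = 200,
                            max_gap = 3600) {
  w0 <- as.numeric(ts_utc(paste(date, "08:00:00")))
  w1 <- as.numeric(ts_utc(paste(date, "23:00:00")))
  any_in_window <- FALSE
  for (i in seq_len(nrow(fixes))) {
    ti <- as.numeric(fixes$t[i])
    if (ti >= w0 && ti <= w1) any_in_window <- TRUE
  }
  if (!any_in_window) return(NA_real_) # no location data that day
  total <- 0
  n <- nrow(fixes)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) {
    t1 <- as.numeric(fixes$t[i]); t2 <- as.numeric(fixes$t[i + 1])
    d1 <- digiphase::haversine_m(fixes$lat[i], fixes$lon[i], home$lat, home$lon)
    d2 <- digiphase::haversine_m(fixes$lat[i + 1], fixes$lon[i + 1],
                                 home$lat, home$lon)
    if (d1 <= home_radius_m && d2 <= home_radius_m && (t2 - t1) <= max_gap) {
      lo <- max(t1, w0); hi <- min(t2, w1)
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total / 60
}

# Reference unlock duration: two-state replay with an explicit state
# variable, then per-session filtering.
oracle_unlock <- function(events, date, max_session = 14400) {
  d0 <- as.numeric(ts_utc(paste(date, "06:00:00")))
  d1 <- d0 + 86400
  open <- NA_real_
  total <- 0
  for (i in seq_len(nrow(events))) {
    t <- as.numeric(events$t[i])
    if (events$state[i] == "unlock") {
      if (is.na(open)) open <- t
    } else {
      if (!is.na(open)) {
        dur <- t - open
        if (open >= d0 && open < d1 && dur <= max_session) total <- total + dur
        open <- NA_real_
      }
    }
  }
  total / 60
}

# Reference Benjamini-Yekutieli: the step-up formula written out directly.
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m * cm / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Reference Dunn z: recompute mean ranks and the tie-corrected variance
# from scratch with explicit tie-group enumeration over values.
oracle_dunn_z <- function(groups, i, j) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), lengths(groups))
  tie3 <- 0
  for (v in unique(pooled)) {
    tv <- sum(pooled == v)
    tie3 <- tie3 + tv^3 - tv
  }
  rb <- tapply(r, g, mean)
  se <- sqrt((N * (N + 1) / 12 - tie3 / (12 * (N - 1))) *
               (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
  (rb[[i]] - rb[[j]]) / se
}

# Random GPS trace around a home point: mixture of at-home and away fixes
# with irregular sampling, for oracle-equivalence tests.
random_trace <- function(date, home, n = 60, away_range = c(150, 5000),
                         home_range = c(0, 120)) {
  secs <- sort(sample(0:86399, n))
  away <- runif(n) < 0.4
  r <- ifelse(away, runif(n, away_range[1], away_range[2]),
              runif(n, home_range[1], home_range[2]))
  th <- runif(n, 0, 2 * pi)
  tibble::tibble(
    t = ts_utc(paste(date, "00:00:00")) + secs,
    lat = home$lat + r * cos(th) / 111194.9265,
    lon = home$lon + r * sin(th) / (111194.9265 * cos(home$lat * pi / 180))
  )
}

# Random phone-event stream (not necessarily alternating).
random_phone_events <- function(date, n = 30) {
  secs <- sort(sample(0:(2 * 86400), n))
  tibble::tibble(
    t = ts_utc(paste(date, "00:00:00")) + secs,
    state = sample(c("unlock", "standby"), n, replace = TRUE)
  )
}

# Three contiguous 20-day phases spanning exactly 60 days.
test_windows_60d <- function() {
  digiphase::phase_windows("2020-02-10", "2020-02-29", "2020-02-10",
                           baseline_start = "2020-01-01")
}

# Three contiguous 30-day phases spanning 90 days.
test_windows_90d <- function() {
  digiphase::phase_windows("2020-03-01", "2020-03-30", "2020-03-01",
                           baseline_start = "2020-01-01")
}
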