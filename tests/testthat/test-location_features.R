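home <- list(lat = 45.4, lon = 9.2)

test_that("haversine distance matches closed forms and is symmetric", {
  expect_identical(haversine_m(45, 9, 45, 9), 0)
  # one degree of equatorial arc = R * pi / 180
  expect_equal(haversine_m(0, 0, 0, 1), 111194.9, tolerance = 0.1 / 111194.9)
  withr::local_seed(3)
  p <- matrix(c(runif(1000, -90, 90), runif(1000, -180, 180),
                runif(1000, -90, 90), runif(1000, -180, 180)), ncol = 4)
  expect_identical(haversine_m(p[, 1], p[, 2], p[, 3], p[, 4]),
                   haversine_m(p[, 3], p[, 4], p[, 1], p[, 2]))
})

test_that("haversine agrees with geosphere at the same Earth radius", {
  skip_if_not_installed("geosphere")
  withr::local_seed(4)
  n <- 500
  a <- cbind(runif(n, -180, 180), runif(n, -89, 89))
  b <- cbind(runif(n, -180, 180), runif(n, -89, 89))
  expect_equal(haversine_m(a[, 2], a[, 1], b[, 2], b[, 1]),
               geosphere::distHaversine(a, b, r = 6371000),
               tolerance = 1e-9)
})

test_that("spurious filter removes double-sided jumps only", {
  mk <- function(lat, lon) {
    tibble::tibble(t = ts_utc("2020-03-01 10:00:00") + 300 * seq_along(lat),
                   lat = lat, lon = lon)
  }
  x <- mk(c(45.0, 51.0, 45.001), c(9.0, 9.0, 9.0))
  expect_equal(filter_spurious(x)$lat, c(45.0, 45.001))
  y <- mk(c(45, 45.1, 45.2), c(9, 9.1, 9.0))
  expect_identical(filter_spurious(y), y)
})

test_that("spurious filter equals the brute-force reference on random walks", {
  withr::local_seed(5)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    lat <- cumsum(rnorm(n, 0, 0.5)) + 45
    lon <- cumsum(rnorm(n, 0, 0.5)) + 9
    spikes <- sample(n, size = max(1, n %/% 6))
    lat[spikes] <- lat[spikes] + sample(c(-10, 10), length(spikes), TRUE)
    x <- tibble::tibble(t = ts_utc("2020-03-01 00:00:00") + 300 * seq_len(n),
                        lat = lat, lon = lon)
    expect_identical(filter_spurious(x), oracle_filter_spurious(x))
  }
})

test_that("home inference follows the last fix's cluster, not the largest", {
  # cluster A: 30 fixes 22:00-02:00 at one place; B: 10 fixes 02:05-03:55
  # elsewhere; the last fix is in B, so home must be B's mean.
  a_t <- ts_utc("2020-03-01 22:00:00") + seq(0, by = 480, length.out = 30)
  b_t <- ts_utc("2020-03-02 02:05:00") + seq(0, by = 733, length.out = 10)
  fixes <- tibble::tibble(
    t = c(a_t, b_t),
    lat = c(rep(45.40, 30), rep(45.48, 10)) + rnorm(40, 0, 1e-5),
    lon = c(rep(9.20, 30), rep(9.30, 10)) + rnorm(40, 0, 1e-5))
  h <- infer_home(fixes, as.Date("2020-03-01"))
  expect_equal(h$lat, 45.48, tolerance = 1e-3)
  expect_equal(h$lon, 9.30, tolerance = 1e-3)
  expect_identical(h$n_cluster_pts, 10L)
})

test_that("home inference handles degenerate and empty nights", {
  one_pt <- tibble::tibble(t = ts_utc("2020-03-01 22:00:00") + (0:9) * 300,
                           lat = 45.4, lon = 9.2)
  h <- infer_home(one_pt, as.Date("2020-03-01"))
  expect_equal(c(h$lat, h$lon), c(45.4, 9.2))
  expect_null(infer_home(one_pt, as.Date("2020-03-05")))
})

test_that("homestay handles the full-window and long-gap cases", {
  d <- as.Date("2020-03-01")
  at_home <- tibble::tibble(
    t = ts_utc("2020-03-01 08:00:00") + seq(0, 15 * 3600, by = 300),
    lat = home$lat, lon = home$lon)
  expect_equal(daily_homestay(at_home, home, d), 900)
  sparse <- tibble::tibble(t = ts_utc(c("2020-03-01 09:00:00",
                                        "2020-03-01 10:30:00")),
                           lat = home$lat, lon = home$lon)
  expect_equal(daily_homestay(sparse, home, d), 0) # 90-min gap excluded
  expect_true(is.na(daily_homestay(at_home, NULL, d)))
})

test_that("homestay equals the brute-force pair enumeration on random traces", {
  withr::local_seed(6)
  d <- as.Date("2020-03-01")
  for (rep in 1:200) {
    x <- random_trace(d, home, n = sample(10:80, 1))
    expect_equal(daily_homestay(x, home, d), oracle_homestay(x, home, d),
                 tolerance = 1e-12)
  }
})

test_that("homestay never exceeds the stay-window length", {
  withr::local_seed(7)
  d <- as.Date("2020-03-01")
  for (rep in 1:50) {
    x <- random_trace(d, home, n = 200)
    expect_lte(daily_homestay(x, home, d), 900)
  }
})

test_that("maximum distance from home behaves like a maximum", {
  d <- as.Date("2020-03-01")
  at_home <- tibble::tibble(t = ts_utc("2020-03-01 12:00:00") + (0:5) * 300,
                            lat = home$lat, lon = home$lon)
  expect_equal(daily_max_distance(at_home, home, d), 0)
  far <- dplyr::bind_rows(at_home, tibble::tibble(
    t = ts_utc("2020-03-01 14:00:00"),
    lat = home$lat + 5000 / 111194.9265, lon = home$lon))
  expect_equal(daily_max_distance(far, home, d), 5000, tolerance = 1e-3)
  farther <- dplyr::bind_rows(far, tibble::tibble(
    t = ts_utc("2020-03-01 15:00:00"),
    lat = home$lat + 9000 / 111194.9265, lon = home$lon))
  expect_gte(daily_max_distance(farther, home, d),
             daily_max_distance(far, home, d))
  night_only <- tibble::tibble(t = ts_utc("2020-03-01 02:00:00"),
                               lat = home$lat, lon = home$lon)
  expect_true(is.na(daily_max_distance(night_only, home, d)))
})

test_that("constant longitude offsets leave home-anchored features unchanged", {
  withr::local_seed(8)
  d <- as.Date("2020-03-01")
  for (rep in 1:20) {
    x <- random_trace(d, home, n = 120, away_range = c(300, 5000))
    hs <- daily_homestay(x, home, d)
    md <- daily_max_distance(x, home, d)
    off <- runif(1, -0.5, 0.5)
    x2 <- dplyr::mutate(x, lon = lon + off)
    home2 <- list(lat = home$lat, lon = home$lon + off)
    expect_identical(daily_homestay(x2, home2, d), hs)
    expect_lt(abs(daily_max_distance(x2, home2, d) - md) / max(md, 1), 1e-6)
  }
})

test_that("a +0.1 degree latitude offset perturbs features by under 1%", {
  withr::local_seed(9)
  d <- as.Date("2020-03-01")
  for (rep in 1:20) {
    x <- random_trace(d, home, n = 120, away_range = c(300, 5000))
    hs <- daily_homestay(x, home, d)
    md <- daily_max_distance(x, home, d)
    x2 <- dplyr::mutate(x, lat = lat + 0.1)
    home2 <- list(lat = home$lat + 0.1, lon = home$lon)
    hs2 <- daily_homestay(x2, home2, d)
    md2 <- daily_max_distance(x2, home2, d)
    expect_lt(abs(hs2 - hs) / max(hs, 1), 0.01)
    expect_lt(abs(md2 - md) / max(md, 1), 0.01)
  }
})
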