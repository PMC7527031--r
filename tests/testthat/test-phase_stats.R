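test_that("phase windows derive prelockdown and baseline from the lockdown", {
  w <- phase_windows("2020-03-21", "2020-05-09", "2020-03-08")
  expect_equal(as.character(w$prelockdown),
               c("2020-01-18", "2020-03-07")) # 50 days ending pre-restriction
  expect_equal(as.character(w$baseline), c("2019-03-21", "2019-05-09"))
  lens <- vapply(w[c("baseline", "prelockdown", "lockdown")],
                 function(x) as.integer(diff(x)) + 1L, integer(1))
  expect_true(all(lens == 50L))
  expect_error(phase_windows("2020-03-21", "2020-05-09", "2020-03-08",
                             baseline_start = "2020-02-01"), "overlap")
})

test_that("Kruskal-Wallis matches the hand-ranked example and stats::kruskal.test", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(rep(5, 4), rep(5, 3), rep(5, 5)))
  expect_equal(c(same$H, same$p), c(0, 1))

  withr::local_seed(15)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    gr <- lapply(seq_len(k), function(i) round(rnorm(sample(5:20, 1)), 1))
    ref <- stats::kruskal.test(unlist(gr),
                               rep(seq_len(k), lengths(gr)))
    kw <- kruskal_wallis(gr)
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Dunn z matches the worked example and an independent reference", {
  dn <- dunn_posthoc(list(1:3, 4:6, 7:9), c(1, 3))
  expect_equal(dn$z, (2 - 8) / sqrt(7.5 * (2 / 3)), tolerance = 1e-12)
  expect_equal(dn$z, -2.683, tolerance = 0.001 / 2.683)

  expect_equal(dunn_posthoc(list(c(1, 2), c(1, 2)), c(1, 2))$z, 0)

  withr::local_seed(16)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    gr <- lapply(seq_len(k), function(i) round(rnorm(sample(4:15, 1)), 1))
    pr <- sample(k, 2)
    z <- dunn_posthoc(gr, pr)$z
    expect_lt(abs(z - oracle_dunn_z(gr, pr[1], pr[2])), 1e-9)
    # antisymmetry in the pair order
    expect_equal(dunn_posthoc(gr, rev(pr))$z, -z)
  }
})

test_that("pooled mean ranks conserve the total rank sum", {
  withr::local_seed(17)
  gr <- lapply(1:3, function(i) round(rnorm(sample(5:15, 1)), 1))
  pooled <- unlist(gr)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(gr), lengths(gr))
  expect_equal(sum(tapply(r, g, mean) * lengths(gr)), N * (N + 1) / 2)
})

test_that("Benjamini-Yekutieli matches the step-up formula", {
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.04)),
               c(0.055, 0.055, 0.0733), tolerance = 0.0001 / 0.055)
  expect_identical(benjamini_yekutieli(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(benjamini_yekutieli(0.03), 0.03) # m = 1, c(1) = 1
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(18)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, oracle_by(p), tolerance = 1e-12)
    # monotone in the raw p-values and never below the BH adjustment
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= stats::p.adjust(p, "BH") - 1e-12))
  }
})

test_that("signed-rank W is min(W+, W-) and p agrees with wilcox.test", {
  ws <- wilcoxon_signed_rank(c(1, -2, 3))
  expect_equal(c(ws$W, ws$W_plus, ws$W_minus), c(2, 4, 2))

  zero <- wilcoxon_signed_rank(rep(0, 10))
  expect_equal(c(zero$W, zero$p), c(0, 1))

  withr::local_seed(19)
  for (rep in 1:50) {
    n <- sample(6:40, 1)
    d <- rnorm(n) # continuous, tie-free
    ws <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = n <= 25, correct = TRUE)
    expect_equal(ws$p, ref$p.value, tolerance = 1e-10)
    expect_equal(min(unname(ref$statistic), n * (n + 1) / 2 -
                       unname(ref$statistic)), ws$W)
  }
  # tied case: normal approximation with tie correction
  d <- c(1, 1, -1, 2, 3, 3, -2, 4, 5, 5, -3, 6, 1, -1, 2, 2, 3, -4, 5, 6,
         7, 7, -5, 8, 9, 9)
  ws <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE))
  expect_equal(ws$p, ref$p.value, tolerance = 1e-10)
})

test_that("assign_phases drops below-minimum days and labels the rest", {
  w <- test_windows_90d()
  series <- tibble::tibble(
    date = seq(as.Date("2020-01-01"), as.Date("2020-03-30"), by = "day"),
    feature = "steps",
    median = 100, q25 = 90, q75 = 110, n = 40L)
  series$median[5] <- NA # a day failing the 20-participant rule
  s <- assign_phases(series, w)
  expect_identical(nrow(s), 89L)
  expect_identical(as.vector(table(s$phase)), c(29L, 30L, 30L))
})

test_that("phase analysis applies gatekeeping and per-family corrections", {
  w <- test_windows_90d()
  cfg <- sim_config(w, n_participants = 40, seed = 101)
  ft <- simulate_feature_table(cfg, behavior_params("lockdown"))
  res <- phase_analysis(ft$features, w)
  kw <- res[res$comparison == "kruskal_wallis", ]
  expect_identical(nrow(kw), 9L)
  expect_true(all(kw$p_adj >= kw$p_raw))
  expect_identical(kw$significant, kw$p_adj < 0.05)
  # only gated features receive post hoc comparisons
  post <- res[res$comparison != "kruskal_wallis", ]
  expect_true(all(post$feature %in% kw$feature[kw$significant]))
  expect_true(all(table(post$feature) == 3))

  # correction family equals the set of features actually tested
  single <- phase_analysis(ft$features, w, features = "steps")
  expect_equal(single$p_adj[single$comparison == "kruskal_wallis"],
               single$p_raw[single$comparison == "kruskal_wallis"])
})

test_that("lockdown shifts yield the expected pre-vs-during sign pattern", {
  w <- test_windows_90d()
  cfg <- sim_config(w, n_participants = 40, seed = 7)
  ft <- simulate_feature_table(cfg, behavior_params("lockdown"))
  res <- phase_analysis(ft$features, w)
  pd <- res[res$comparison == "prelockdown_vs_lockdown", ]
  # features that increase during lockdown carry negative z
  up <- c("homestay_min", "sleep_min", "bedtime_min", "unlock_min",
          "social_min")
  expect_true(all(pd$statistic[pd$feature %in% up] < 0))
  expect_true(all(pd$statistic[!pd$feature %in% up] > 0))
})

test_that("identical subgroup series give W = 0 and p = 1", {
  w <- test_windows_90d()
  dates <- seq(w$lockdown[1], w$lockdown[2], by = "day")
  tab <- tidyr::expand_grid(pid = sprintf("P%03d", 1:8), date = dates)
  tab$homestay_min <- 600
  tab$steps <- 5000
  meta <- tibble::tibble(pid = sprintf("P%03d", 1:8),
                         age = c(30, 30, 30, 30, 60, 60, 60, 60),
                         gender = rep(c("male", "female"), 4),
                         bmi = 24, degree = rep(c(TRUE, FALSE), 4),
                         cohort = "SYN")
  res <- subgroup_analysis(tab, meta, w, factors = c("age", "gender"))
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$statistic == 0))
  expect_true(all(!res$significant))
})

test_that("a young-group homestay shift is recovered by the age factor", {
  w <- test_windows_90d()
  cfg <- sim_config(w, n_participants = 40, seed = 11)
  sh <- list(feature = "homestay_min", selector = function(m) m$age < 45,
             amount = 120, phase = "lockdown")
  ft <- simulate_feature_table(cfg, behavior_params("lockdown"), shift = sh)
  res <- subgroup_analysis(ft$features, ft$metadata, w)
  age_row <- res[res$factor == "age" & res$feature == "homestay_min", ]
  expect_true(age_row$significant)
  expect_identical(age_row$direction, 1) # young group higher
})
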