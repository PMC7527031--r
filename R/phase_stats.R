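# Phase construction and hypothesis testing: Kruskal-Wallis across
# baseline / prelockdown / lockdown on the daily cohort medians, post hoc
# Dunn tests gated on the corrected omnibus result, Benjamini-Yekutieli
# multiple-testing correction, and paired subgroup Wilcoxon signed-rank
# comparisons during lockdown.

#' Construct the three analysis phase windows
#'
#' The lockdown window is given; the prelockdown window has the same length
#' and ends the day before the first restrictive measure; the baseline
#' window defaults to the same calendar period one year earlier (to
#' suppress seasonal variability) but can be set explicitly for cohorts
#' without a full prior year of data.
#'
#' @param lockdown_start,lockdown_end Lockdown dates (inclusive).
#' @param first_restriction Date of the first restrictive measure; must not
#'   be after `lockdown_start`.
#' @param baseline_start Optional explicit baseline start date.
#' @return A list of class `phase_windows` with Date vectors `baseline`,
#'   `prelockdown`, `lockdown` (start, end) and `first_restriction`.
#' @export
#' @examples
#' phase_windows("2020-03-21", "2020-05-09", "2020-03-08")
phase_windows <- function(lockdown_start, lockdown_end, first_restriction,
                          baseline_start = NULL) {
  lockdown_start <- as.Date(lockdown_start)
  lockdown_end <- as.Date(lockdown_end)
  first_restriction <- as.Date(first_restriction)
  stopifnot(lockdown_start <= lockdown_end,
            first_restriction <= lockdown_start)
  len <- as.integer(lockdown_end - lockdown_start) + 1L
  pre_end <- first_restriction - 1L
  pre_start <- pre_end - len + 1L
  base_start <- if (is.null(baseline_start)) {
    md <- format(lockdown_start, "%m-%d")
    if (md == "02-29") md <- "02-28"
    as.Date(paste0(as.integer(format(lockdown_start, "%Y")) - 1L, "-", md))
  } else as.Date(baseline_start)
  base_end <- base_start + len - 1L
  w <- structure(list(baseline = c(base_start, base_end),
                      prelockdown = c(pre_start, pre_end),
                      lockdown = c(lockdown_start, lockdown_end),
                      first_restriction = first_restriction),
                 class = "phase_windows")
  if (base_end >= pre_start) {
    stop("baseline window overlaps the prelockdown window", call. = FALSE)
  }
  w
}

#' Phase labels for calendar dates
#'
#' @param dates Date vector.
#' @param windows A [phase_windows()].
#' @return Character vector (`"baseline"`, `"prelockdown"`, `"lockdown"`,
#'   or `NA` outside every window).
#' @export
phase_of <- function(dates, windows) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (ph in c("baseline", "prelockdown", "lockdown")) {
    out[dates >= windows[[ph]][1] & dates <= windows[[ph]][2]] <- ph
  }
  out
}

#' Per-phase daily-median samples
#'
#' Labels each day of a cohort daily series with its phase and keeps the
#' days falling in a phase with a non-missing median (days failing the
#' minimum-participant rule contribute no sample).
#'
#' @param series Output of [cohort_daily()].
#' @param windows A [phase_windows()].
#' @return Tibble: `feature`, `phase`, `date`, `value`.
#' @export
assign_phases <- function(series, windows) {
  series |>
    dplyr::mutate(phase = phase_of(.data$date, windows)) |>
    dplyr::filter(!is.na(.data$phase), !is.na(.data$median)) |>
    dplyr::transmute(.data$feature,
                     phase = factor(.data$phase,
                                    c("baseline", "prelockdown", "lockdown")),
                     .data$date, value = .data$median)
}

# Pooled mid-ranks plus the tie term sum(t^3 - t) over tie groups. Tie
# groups are read off the mid-ranks (tied values share a unique mid-rank),
# which avoids coercing doubles through table()'s character representation.
.pooled_ranks <- function(x) {
  r <- rank(x)
  t <- table(r)
  list(r = r, tie3 = sum(t^3 - t))
}

#' Kruskal-Wallis test with tie correction
#'
#' Rank-based k-sample test; the statistic is divided by the tie-correction
#' factor `1 - sum(t^3 - t) / (N^3 - N)` and referred to a chi-square
#' distribution with k - 1 degrees of freedom. When every observation is
#' identical the statistic is defined as 0 (p = 1).
#'
#' @param groups List of k >= 2 numeric vectors.
#' @return List with `H`, `p`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9)) # H = 7.2
kruskal_wallis <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  n <- lengths(groups)
  stopifnot(all(n >= 1))
  N <- sum(n)
  stopifnot(N >= k)
  pooled <- unlist(groups, use.names = FALSE)
  pr <- .pooled_ranks(pooled)
  g <- rep(seq_len(k), n)
  rbar <- tapply(pr$r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  corr <- 1 - pr$tie3 / (N^3 - N)
  if (corr <= 0) return(list(H = 0, p = 1, df = k - 1L))
  H <- H / corr
  list(H = H, p = stats::pchisq(H, k - 1L, lower.tail = FALSE), df = k - 1L)
}

#' Post hoc Dunn test for one pair of groups
#'
#' Pairwise z statistic on the mean ranks of the *pooled* ranking across all
#' k groups, with tie-corrected variance. With `pair = c(i, j)` and i the
#' chronologically earlier group, a feature that increases in the later
#' group yields a negative z.
#'
#' @param groups List of numeric vectors (all k groups, so the pooled
#'   ranking matches the omnibus test).
#' @param pair Integer pair (i, j) of group indices to compare.
#' @return List with `z`, `p` (two-sided normal).
#' @export
dunn_posthoc <- function(groups, pair) {
  stopifnot(length(pair) == 2, all(pair >= 1), all(pair <= length(groups)))
  n <- lengths(groups)
  if (any(n[pair] == 0L)) stop("empty group in Dunn comparison", call. = FALSE)
  N <- sum(n)
  pooled <- unlist(groups, use.names = FALSE)
  pr <- .pooled_ranks(pooled)
  g <- rep(seq_along(groups), n)
  rbar <- tapply(pr$r, g, mean)
  v <- (N * (N + 1) / 12 - pr$tie3 / (12 * (N - 1))) *
    (1 / n[pair[1]] + 1 / n[pair[2]])
  if (v <= 0) return(list(z = 0, p = 1))
  z <- (rbar[[pair[1]]] - rbar[[pair[2]]]) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' the Benjamini-Hochberg adjustment inflated by `c(m) = sum(1/l, l=1..m)`,
#' capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' benjamini_yekutieli(c(0.01, 0.02, 0.04))
benjamini_yekutieli <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Wilcoxon signed-rank test reporting W = min(W+, W-)
#'
#' Zero differences are dropped, ties in |d| are mid-ranked; the p-value is
#' exact (signed-rank distribution) for 25 or fewer nonzero pairs without
#' ties, otherwise a normal approximation with tie and continuity
#' corrections. When every difference is zero, W = 0 and p = 1.
#'
#' @param x,y Paired numeric vectors (or differences in `x` with
#'   `y = NULL`).
#' @return List with `W`, `W_plus`, `W_minus`, `n` (nonzero pairs), `p`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(W = 0, W_plus = 0, W_minus = 0, n = 0L, p = 1))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25 && !ties) {
    p <- min(1, 2 * stats::psignrank(W, n))
  } else {
    mu <- n * (n + 1) / 4
    t <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t^3 - t) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(W = W, W_plus = w_plus, W_minus = w_minus, n = n, p = min(1, p))
}

#' Phase comparison of every feature
#'
#' Computes the cohort's daily medians (under the minimum-participant
#' rule), splits them into the three phases, and runs a Kruskal-Wallis test
#' per feature. Omnibus p-values are Benjamini-Yekutieli corrected across
#' the features actually tested; only features significant after that
#' correction receive the three pairwise post hoc Dunn tests, whose
#' p-values are Benjamini-Yekutieli corrected across the three comparisons
#' within the feature (gatekeeping).
#'
#' @param table Participant-day feature table.
#' @param windows A [phase_windows()].
#' @param features Feature columns to test.
#' @param min_n Minimum participants per day for the daily median.
#' @param alpha Significance level applied to corrected p-values.
#' @return Tibble: `feature`, `comparison` (`"kruskal_wallis"` or
#'   `"<phase_i>_vs_<phase_j>"`), `statistic` (H or z), `p_raw`, `p_adj`,
#'   `significant`.
#' @export
phase_analysis <- function(table, windows, features = feature_names(),
                           min_n = 20, alpha = 0.05) {
  series <- cohort_daily(table, features, min_n)
  samples <- assign_phases(series, windows)
  phases <- c("baseline", "prelockdown", "lockdown")
  per_feature <- lapply(features, function(f) {
    gr <- lapply(phases, function(ph) {
      samples$value[samples$feature == f & samples$phase == ph]
    })
    names(gr) <- phases
    if (sum(lengths(gr) > 0) < 2) {
      message("feature ", f, " has fewer than two non-empty phases; skipped")
      return(NULL)
    }
    gr
  })
  names(per_feature) <- features
  tested <- features[!vapply(per_feature, is.null, logical(1))]
  if (length(tested) == 0L) {
    return(tibble::tibble(feature = character(), comparison = character(),
                          statistic = numeric(), p_raw = numeric(),
                          p_adj = numeric(), significant = logical()))
  }
  kw <- lapply(per_feature[tested], function(gr) {
    kruskal_wallis(gr[lengths(gr) > 0])
  })
  kw_adj <- benjamini_yekutieli(vapply(kw, `[[`, numeric(1), "p"))
  out <- tibble::tibble(
    feature = tested,
    comparison = "kruskal_wallis",
    statistic = vapply(kw, `[[`, numeric(1), "H"),
    p_raw = vapply(kw, `[[`, numeric(1), "p"),
    p_adj = kw_adj,
    significant = kw_adj < alpha)
  pair_idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  posthoc <- lapply(tested[kw_adj < alpha], function(f) {
    gr <- per_feature[[f]]
    keep <- lengths(gr) > 0
    grk <- gr[keep]
    ok_pairs <- Filter(function(pq) all(phases[pq] %in% names(grk)), pair_idx)
    dn <- lapply(ok_pairs, function(pq) {
      ij <- match(phases[pq], names(grk))
      dunn_posthoc(grk, ij)
    })
    adj <- benjamini_yekutieli(vapply(dn, `[[`, numeric(1), "p"))
    tibble::tibble(
      feature = f,
      comparison = vapply(ok_pairs, function(pq) {
        paste0(phases[pq[1]], "_vs_", phases[pq[2]])
      }, character(1)),
      statistic = vapply(dn, `[[`, numeric(1), "z"),
      p_raw = vapply(dn, `[[`, numeric(1), "p"),
      p_adj = adj,
      significant = adj < alpha)
  })
  dplyr::bind_rows(out, posthoc)
}

.subgroup_split <- function(metadata, factor) {
  switch(factor,
    age = list(a = metadata$pid[metadata$age < 45],
               b = metadata$pid[metadata$age >= 45],
               label = "young_vs_older"),
    gender = list(a = metadata$pid[metadata$gender == "male"],
                  b = metadata$pid[metadata$gender == "female"],
                  label = "male_vs_female"),
    bmi = list(a = metadata$pid[metadata$bmi < 25],
               b = metadata$pid[metadata$bmi >= 25],
               label = "low_vs_high_bmi"),
    degree = list(a = metadata$pid[metadata$degree],
                  b = metadata$pid[!metadata$degree],
                  label = "degree_vs_nondegree"),
    young_men = list(
      a = metadata$pid[metadata$gender == "male" & metadata$age < 45],
      b = metadata$pid[!(metadata$gender == "male" & metadata$age < 45)],
      label = "young_men_vs_rest"),
    stop("unknown subgroup factor: ", factor, call. = FALSE)
  )
}

#' Subgroup comparison of homestay and steps during lockdown
#'
#' For each factor (age, gender, BMI, degree, young men) the cohort is
#' split into two subgroups; each subgroup's cross-participant daily median
#' is computed for every lockdown day, the two series are paired by
#' calendar day (days where either side is missing are dropped), and a
#' Wilcoxon signed-rank test is run per feature. p-values are
#' Benjamini-Yekutieli corrected across all factor-feature combinations
#' (5 x 2 = 10 by default). `method = "rank_sum"` instead pools the two
#' subgroups' daily medians into an unpaired rank-sum test.
#'
#' @param table Participant-day feature table.
#' @param metadata Participant metadata tibble.
#' @param windows A [phase_windows()].
#' @param features Features to test (homestay and daily steps).
#' @param factors Subgroup factors to test.
#' @param min_n Minimum participants per subgroup per day for the daily
#'   median (1 by default: subgroups are small).
#' @param alpha Significance level applied to corrected p-values.
#' @param method `"signed_rank"` (paired by day) or `"rank_sum"`.
#' @return Tibble: `feature`, `factor`, `comparison`, `statistic` (W),
#'   `n_pairs`, `direction` (sign of the median paired difference, group A
#'   minus group B), `p_raw`, `p_adj`, `significant`.
#' @export
subgroup_analysis <- function(table, metadata, windows,
                              features = c("homestay_min", "steps"),
                              factors = c("age", "gender", "bmi", "degree",
                                          "young_men"),
                              min_n = 1, alpha = 0.05,
                              method = c("signed_rank", "rank_sum")) {
  method <- match.arg(method)
  lock <- table[table$date >= windows$lockdown[1] &
                  table$date <= windows$lockdown[2], , drop = FALSE]
  daily_median <- function(pids, feature) {
    sub <- lock[lock$pid %in% pids, c("date", feature)]
    names(sub)[2] <- "value"
    sub |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::summarise(value = stats::median(.data$value),
                       n = dplyr::n(), .by = "date") |>
      dplyr::filter(.data$n >= min_n)
  }
  rows <- list()
  for (f in features) {
    for (fac in factors) {
      sp <- .subgroup_split(metadata, fac)
      a <- daily_median(sp$a, f)
      b <- daily_median(sp$b, f)
      paired <- dplyr::inner_join(a, b, by = "date",
                                  suffix = c("_a", "_b"))
      if (method == "signed_rank") {
        ts <- wilcoxon_signed_rank(paired$value_a, paired$value_b)
        stat <- ts$W
        n_pairs <- ts$n
        p <- ts$p
      } else {
        ht <- suppressWarnings(stats::wilcox.test(paired$value_a,
                                                  paired$value_b))
        stat <- unname(ht$statistic)
        n_pairs <- nrow(paired)
        p <- ht$p.value
      }
      d <- paired$value_a - paired$value_b
      d <- d[!is.na(d) & d != 0]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature = f, factor = fac, comparison = sp$label,
        statistic = stat, n_pairs = n_pairs,
        direction = if (length(d) == 0L) 0 else sign(stats::median(d)),
        p_raw = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- benjamini_yekutieli(out$p_raw)
  out$significant <- out$p_adj < alpha
  out
}
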