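sim_exp <- function(n, rate, cens = 8, seed = 1) {
  set.seed(seed)
  t <- rexp(n, rate)
  tibble::tibble(time = pmin(t, cens), event = t <= cens)
}

test_that("maximal smoothing returns the constant events/person-time rate", {
  d <- sim_exp(3000, 0.05)
  h <- smooth_hazard(d$time, d$event, df = 1)
  crude <- sum(d$event) / sum(d$time)
  expect_true(all(abs(h$curve$hazard - crude) < 1e-8))
})

test_that("a constant hazard is recovered within the pointwise band", {
  d <- sim_exp(20000, 0.02, seed = 1)
  h <- smooth_hazard(d$time, d$event)
  cv <- h$curve
  inside <- mean(cv$band_low <= 0.02 & 0.02 <= cv$band_high)
  expect_gte(inside, 0.90)
})

test_that("cause-specific hazards add up to the all-cause hazard", {
  set.seed(3)
  n <- 20000
  t1 <- rexp(n, 0.015); t2 <- rexp(n, 0.010)   # two competing causes
  t <- pmin(t1, t2, 8)
  cause <- ifelse(t1 <= t2, 1L, 2L) * (pmin(t1, t2) <= 8)
  ha <- smooth_hazard(t, cause > 0, df = 4)
  h1 <- smooth_hazard(t, cause == 1, df = 4)
  h2 <- smooth_hazard(t, cause == 2, df = 4)
  grid_sum <- h1$curve$hazard + h2$curve$hazard
  rel <- abs(grid_sum - ha$curve$hazard) / ha$curve$hazard
  expect_lt(mean(rel), 0.10)
})

test_that("hazard estimation refuses empty event sets", {
  d <- sim_exp(100, 0.001)
  expect_error(smooth_hazard(d$time, rep(FALSE, 100)),
               class = "carcmort_hazard_error")
})

test_that("survival implied by the smoothed hazard matches Kaplan-Meier", {
  d <- sim_exp(10000, 0.08, seed = 4)
  h <- smooth_hazard(d$time, d$event, df = 4)
  km <- km_estimate(d$time, d$event)
  cum <- cumsum(h$curve$hazard) * (1 / 12)
  s_h <- exp(-cum)
  idx <- findInterval(h$curve$time, km$time)
  s_km <- km$survival[idx]
  expect_lt(max(abs(s_h - s_km)), 0.02)
})

test_that("hazard bands narrow as the sample grows", {
  w <- vapply(c(2000, 20000), function(n) {
    d <- sim_exp(n, 0.05, seed = 6)
    h <- smooth_hazard(d$time, d$event, df = 4)
    mean(h$curve$band_high - h$curve$band_low)
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("Kaplan-Meier reproduces a hand product-limit table", {
  # 10 subjects; deaths at 1, 2 (x2), 4, 7; censorings at 3, 5, 5, 6, 8
  time <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  event <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0)
  km <- km_estimate(time, event)
  # hand computation: S(1)=9/10; S(2)=9/10*7/9=0.7; S(4)=0.7*5/6;
  # S(7)=0.7*5/6*1/2
  expect_equal(km$survival[km$time == 1], 0.9)
  expect_equal(km$survival[km$time == 2], 0.7)
  expect_equal(km$survival[km$time == 4], 0.7 * 5 / 6)
  expect_equal(km$survival[km$time == 7], 0.7 * 5 / 6 * 0.5)
  expect_equal(km$survival[1], 1)
  expect_true(all(diff(km$survival) <= 1e-12))
})

test_that("Kaplan-Meier limiting cases", {
  none <- km_estimate(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(none$survival == 1))
  one <- km_estimate(5, 1)
  expect_equal(one$survival[one$time == 5], 0)
})

test_that("log-rank is zero for identical groups and powerful when apart", {
  d <- sim_exp(200, 0.2, seed = 7)
  both <- rbind(d, d)
  g <- rep(c("a", "b"), each = 200)
  lr <- log_rank(both$time, both$event, g)
  expect_lt(lr$statistic, 1e-9)
  expect_equal(lr$df, 1)
  # power at exponential rates 0.1 vs 0.3, n = 500 per arm
  set.seed(8)
  rejections <- 0
  for (i in 1:200) {
    t1 <- pmin(rexp(500, 0.1), 5); t2 <- pmin(rexp(500, 0.3), 5)
    ev <- c(rexp(0), t1 < 5, t2 < 5)
    p <- log_rank(c(t1, t2), c(t1 < 5, t2 < 5),
                  rep(c("a", "b"), each = 500))$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 200, 0.9)
})

test_that("the permutation null of the log-rank matches chi-square(1)", {
  set.seed(9)
  d <- sim_exp(300, 0.15, seed = 9)
  g0 <- rep(c("a", "b"), each = 150)
  stats <- vapply(1:300, function(i) {
    log_rank(d$time, d$event, sample(g0))$statistic
  }, numeric(1))
  q95 <- unname(stats::quantile(stats, 0.95))
  expect_lt(abs(q95 - stats::qchisq(0.95, 1)) / stats::qchisq(0.95, 1), 0.30)
})

test_that("empty groups are dropped with a warning", {
  d <- sim_exp(100, 0.2, seed = 10)
  g <- factor(rep(c("a", "b"), each = 50), levels = c("a", "b", "c"))
  expect_warning(lr <- log_rank(d$time, d$event, g), "empty")
  expect_equal(lr$n_groups, 2)
})

test_that("the reduced cohort applies the follow-up and censoring rules", {
  wnd <- as.Date(c("2009-01-01", "2019-01-01"))
  ep <- tibble::tibble(
    person_uid = c("A", "A", "B", "B", "C", "C", "C"),
    location = c("closed", "post_release", "closed", "post_release",
                 "closed", "semi_open", "post_release"),
    start = as.Date(c("2010-01-01", "2011-01-01", "2015-06-01", "2016-06-01",
                      "2010-01-01", "2011-01-01", "2012-01-01")),
    end = as.Date(c("2011-01-01", "2019-01-01", "2016-06-01", "2019-01-01",
                    "2011-01-01", "2012-01-01", "2019-01-01")),
    end_reason = c("release", "study_end", "release", "study_end",
                   "transfer", "release", "study_end"))
  rc <- build_reduced_cohort(ep, study_window = wnd)
  # B released less than 5 years before the window end: excluded
  expect_setequal(rc$person_uid, c("A", "C"))
  expect_true(all(rc$time <= 5))
  # C: two custody episodes of one year each -> cumulative 2 years
  expect_equal(rc$cum_incarceration_years[rc$person_uid == "C"], 2,
               tolerance = 0.01)
  # death within the horizon is an event at its post-release time
  deaths <- tibble::tibble(person_uid = "A",
                           death_date = as.Date("2013-01-01"),
                           broad_cause = "violence")
  rc2 <- build_reduced_cohort(ep, deaths, study_window = wnd)
  a <- rc2[rc2$person_uid == "A", ]
  expect_true(a$event)
  expect_equal(a$time, 2, tolerance = 0.01)
  expect_equal(a$cause, "violence")
})

test_that("reduced-cohort inclusion matches a brute-force truth filter", {
  coh <- clean_cohort()
  wnd <- coh$config$study_window
  ep <- build_episodes(truth_events(coh), wnd)
  rc <- build_reduced_cohort(ep, study_window = wnd)
  # oracle straight from the truth episodes
  last_rel <- coh$truth$episodes |>
    dplyr::filter(state == "post_release") |>
    dplyr::group_by(person_uid) |>
    dplyr::summarise(last = max(start))
  wy <- as.numeric(diff(wnd)) / 365.25
  expected <- last_rel$person_uid[last_rel$last <= wy - 5]
  expect_setequal(rc$person_uid, expected)
})

test_that("tidy, glance and autoplot work on hazard fits", {
  d <- sim_exp(2000, 0.1, seed = 11)
  h <- smooth_hazard(d$time, d$event, df = 4)
  td <- tidy(h)
  expect_true(all(c("time", "hazard", "band_low", "band_high") %in%
                    names(td)))
  gl <- glance(h)
  expect_equal(gl$n_events, sum(d$event))
  p <- autoplot(h)
  expect_s3_class(p, "ggplot")
})
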