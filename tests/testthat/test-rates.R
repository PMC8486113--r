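test_that("rates and exact Poisson intervals follow the count arithmetic", {
  r0 <- age_specific_rate(0, 100)
  expect_equal(r0$rate_per_100k, 0)
  expect_equal(r0$ci_low, 0)
  r <- age_specific_rate(10, 1000)
  expect_equal(r$rate_per_100k, 1000)
  expect_error(age_specific_rate(3, 0), class = "carcmort_rate_error")
})

test_that("the exact rate CI matches direct Poisson tail inversion", {
  # oracle: smallest/largest mean whose tail probability reaches 2.5%
  d <- 7; py <- 500
  lo <- uniroot(function(m) ppois(d - 1, m, lower.tail = FALSE) - 0.025,
                c(1e-6, 50), tol = 1e-10)$root
  hi <- uniroot(function(m) ppois(d, m) - 0.025, c(1e-6, 50),
                tol = 1e-10)$root
  got <- age_specific_rate(d, py)
  expect_equal(got$ci_low, lo / py * 1e5, tolerance = 1e-6)
  expect_equal(got$ci_high, hi / py * 1e5, tolerance = 1e-6)
})

std_weights2 <- tibble::tibble(age_bin = c("a", "b"), weight = c(0.5, 0.5))

test_that("standardization is a weighted mean with expected invariances", {
  # equal age-specific rates: ASR equals that rate for any weights
  ar <- age_specific_rate(c(10, 40), c(10000, 40000),
                          age_bin = c("a", "b"))
  w <- tibble::tibble(age_bin = c("a", "b"), weight = c(0.37, 0.63))
  expect_equal(standardize(ar, w)$rate_per_100k, 100)
  # hand arithmetic: rates 100 and 300 at half weights -> 200
  ar2 <- age_specific_rate(c(10, 30), c(10000, 10000),
                           age_bin = c("a", "b"))
  expect_equal(standardize(ar2, std_weights2)$rate_per_100k, 200)
  # permuting bins changes nothing
  expect_equal(standardize(ar2[2:1, ], std_weights2)$rate_per_100k, 200)
  # bounded by the extreme age-specific rates
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    d <- rpois(k, 20); py <- runif(k, 1000, 50000)
    wts <- runif(k); wts <- wts / sum(wts)
    ar3 <- age_specific_rate(d, py, age_bin = letters[1:k])
    asr <- standardize(ar3, tibble::tibble(age_bin = letters[1:k],
                                           weight = wts))
    expect_gte(asr$rate_per_100k, min(ar3$rate_per_100k) - 1e-9)
    expect_lte(asr$rate_per_100k, max(ar3$rate_per_100k) + 1e-9)
  }
  # a weighted bin missing from the rates is an error
  expect_error(standardize(ar2[1, ], std_weights2), "missing")
})

test_that("exact two-sample rate ratio matches tail-inversion oracle", {
  expect_equal(irr_exact(5, 100, 5, 100)$irr, 1.0)
  got <- irr_exact(10, 100, 5, 100)
  expect_equal(got$irr, 2.0)
  # oracle: invert conditional binomial tails (d1 = 10 of n = 15) by
  # bisection on the success probability, then transform to the ratio scale
  p_lo <- uniroot(function(p) pbinom(10 - 1, 15, p, lower.tail = FALSE) -
                    0.025, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  p_hi <- uniroot(function(p) pbinom(10, 15, p) - 0.025,
                  c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(got$ci_low, p_lo / (1 - p_lo), tolerance = 1e-7)
  expect_equal(got$ci_high, p_hi / (1 - p_hi), tolerance = 1e-7)
  # swapping the groups inverts the ratio and reflects the interval
  rev <- irr_exact(5, 100, 10, 100)
  expect_equal(rev$irr, 1 / got$irr)
  expect_equal(rev$ci_low, 1 / got$ci_high, tolerance = 1e-9)
  expect_equal(rev$ci_high, 1 / got$ci_low, tolerance = 1e-9)
  # zero reference deaths: flagged infinite upper bound
  z <- irr_exact(3, 100, 0, 100)
  expect_true(z$d0_zero)
  expect_equal(z$ci_high, Inf)
})

test_that("exact rate-ratio intervals are conservative (coverage >= nominal)", {
  set.seed(14)
  rho <- 2.5; py1 <- 400; py0 <- 900; base <- 0.01
  hits <- 0; n <- 400
  for (i in seq_len(n)) {
    d1 <- rpois(1, base * rho * py1); d0 <- rpois(1, base * py0)
    if (d1 + d0 == 0) { hits <- hits + 1; next }
    ci <- irr_exact(d1, py1, d0, py0)
    if (ci$ci_low <= rho && rho <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95 - 1e-9)
})

test_that("standardized rate ratios behave at the limits", {
  ar <- age_specific_rate(c(12, 33), c(9000, 21000), age_bin = c("a", "b"))
  asr <- standardize(ar, std_weights2)
  same <- irr_standardized(asr, asr)
  expect_equal(same$irr, 1.0)
  expect_lte(same$ci_low, 1); expect_gte(same$ci_high, 1)
  # single stratum: the point estimate reduces to the crude ratio
  a1 <- standardize(age_specific_rate(14, 1000, age_bin = "a"),
                    tibble::tibble(age_bin = "a", weight = 1))
  a0 <- standardize(age_specific_rate(7, 2000, age_bin = "a"),
                    tibble::tibble(age_bin = "a", weight = 1))
  expect_equal(irr_standardized(a1, a0)$irr,
               irr_exact(14, 1000, 7, 2000)$irr)
  expect_error(
    irr_standardized(a1, standardize(age_specific_rate(0, 1000,
                                                       age_bin = "a"),
                                     tibble::tibble(age_bin = "a",
                                                    weight = 1))),
    class = "carcmort_rate_error")
})

test_that("F-interval coverage for a standardized ratio is near nominal", {
  set.seed(15)
  ratio <- 2.0
  w <- tibble::tibble(age_bin = c("a", "b", "c"),
                      weight = c(0.5, 0.3, 0.2))
  base_r <- c(0.002, 0.005, 0.012)
  py1 <- c(4000, 2500, 1200); py0 <- c(30000, 22000, 12000)
  hits <- 0; n <- 1000
  for (i in seq_len(n)) {
    d1 <- rpois(3, base_r * ratio * py1)
    d0 <- rpois(3, base_r * py0)
    if (sum(d0) == 0) next
    asr1 <- standardize(age_specific_rate(d1, py1,
                                          age_bin = c("a", "b", "c")), w)
    asr0 <- standardize(age_specific_rate(d0, py0,
                                          age_bin = c("a", "b", "c")), w)
    ci <- irr_standardized(asr1, asr0)
    if (ci$ci_low <= ratio && ratio <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n, 0.93)
})
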