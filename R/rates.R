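# Mortality rates and rate ratios. Single rates get exact Poisson
# (chi-square) confidence intervals; directly standardized rates get
# gamma-approximation intervals for weighted sums of Poisson counts;
# two-sample rate ratios get exact conditional-binomial intervals; ratios of
# standardized rates get F-distribution intervals via the equivalent-count
# approximation.

#' Rate with exact Poisson confidence interval
#'
#' Rate per 100,000 person-years with the exact (chi-square quantile)
#' interval for a Poisson count: lower `qchisq(a/2, 2d)/2/py`, upper
#' `qchisq(1-a/2, 2d+2)/2/py`.
#'
#' @param deaths event count.
#' @param person_years person-time at risk (> 0).
#' @param conf_level confidence level.
#' @param age_bin optional label carried through.
#' @return one-row tibble: `age_bin`, `deaths`, `person_years`,
#'   `rate_per_100k`, `ci_low`, `ci_high`.
#' @export
age_specific_rate <- function(deaths, person_years, conf_level = 0.95,
                              age_bin = "all") {
  if (any(person_years <= 0)) {
    abort("person_years must be positive; rate undefined",
          class = "carcmort_rate_error")
  }
  a <- 1 - conf_level
  lo <- ifelse(deaths == 0, 0, qchisq(a / 2, 2 * deaths) / 2)
  hi <- qchisq(1 - a / 2, 2 * deaths + 2) / 2
  tibble(age_bin = age_bin, deaths = deaths, person_years = person_years,
         rate_per_100k = deaths / person_years * 1e5,
         ci_low = lo / person_years * 1e5,
         ci_high = hi / person_years * 1e5)
}

#' Directly standardized rate
#'
#' ASR = sum of `weights * rate_a` over age bins; the interval uses the
#' gamma approximation for a weighted sum of Poisson counts (shape from the
#' equivalent-count ratio ASR^2 / variance, with the usual max-weight
#' adjustment of the upper bound).
#'
#' @param age_rates tibble from [age_specific_rate()] with one row per age
#'   bin (column `age_bin`).
#' @param weights tibble `age_bin`, `weight`; weights sum to 1.
#' @param conf_level confidence level.
#' @return one-row tibble: `rate_per_100k`, `ci_low`, `ci_high`, `deaths`
#'   (total), `var_rate` (variance of the ASR per 100k^2), `equiv_deaths`.
#' @export
standardize <- function(age_rates, weights, conf_level = 0.95) {
  if (abs(sum(weights$weight) - 1) > 1e-6) {
    abort("standard weights must sum to 1")
  }
  nz <- weights[weights$weight > 0, ]
  missing_bins <- setdiff(nz$age_bin, age_rates$age_bin)
  if (length(missing_bins) > 0) {
    abort(paste("age bins with nonzero weight missing from rates:",
                paste(missing_bins, collapse = ", ")))
  }
  d <- left_join(weights, age_rates, by = "age_bin") |>
    mutate(deaths = dplyr::coalesce(.data$deaths, 0),
           person_years = dplyr::coalesce(.data$person_years, Inf))
  # per-100k scale throughout
  asr <- sum(d$weight * d$deaths / d$person_years) * 1e5
  v <- sum((d$weight / d$person_years)^2 * d$deaths) * 1e10
  wmax <- max(d$weight / d$person_years) * 1e5
  a <- 1 - conf_level
  if (v > 0) {
    lo <- v / (2 * asr) * qchisq(a / 2, 2 * asr^2 / v)
    hi <- (v + wmax^2) / (2 * (asr + wmax)) *
      qchisq(1 - a / 2, 2 * (asr + wmax)^2 / (v + wmax^2))
  } else {
    lo <- 0
    hi <- if (asr > 0) asr else wmax / 2 * qchisq(1 - a / 2, 2)
  }
  tibble(rate_per_100k = asr, ci_low = lo, ci_high = hi,
         deaths = sum(d$deaths),
         var_rate = v,
         equiv_deaths = if (v > 0) asr^2 / v else sum(d$deaths))
}

#' Exact two-sample Poisson rate ratio
#'
#' Conditional on the total count, the exposed count is binomial with
#' success probability `py1 * rho / (py1 * rho + py0)`; inverting the exact
#' Clopper-Pearson limits for that probability yields exact limits for the
#' rate ratio rho.
#'
#' @param d1,py1 exposed count and person-time.
#' @param d0,py0 reference count and person-time.
#' @param conf_level confidence level.
#' @return one-row tibble: `irr`, `ci_low`, `ci_high`, `method`
#'   (`"poisson_exact"`), `d0_zero` flag (upper bound infinite).
#' @export
irr_exact <- function(d1, py1, d0, py0, conf_level = 0.95) {
  stopifnot(py1 > 0, py0 > 0)
  if (d1 + d0 == 0) {
    abort("no events in either group; rate ratio undefined",
          class = "carcmort_rate_error")
  }
  a <- 1 - conf_level
  p_lo <- if (d1 == 0) 0 else qbeta(a / 2, d1, d0 + 1)
  p_hi <- if (d0 == 0) 1 else qbeta(1 - a / 2, d1 + 1, d0)
  to_rho <- function(p) p / (1 - p) * py0 / py1
  tibble(irr = (d1 / py1) / (d0 / py0),
         ci_low = to_rho(p_lo),
         ci_high = if (d0 == 0) Inf else to_rho(p_hi),
         method = "poisson_exact",
         d0_zero = d0 == 0)
}

#' Ratio of directly standardized rates with F-distribution interval
#'
#' The ratio of two standardized rates built on the same standard weights.
#' Each rate is reduced to an equivalent Poisson count `d* = ASR^2 / var`
#' (the count a single Poisson observation with the same relative variance
#' would have); exact two-count Poisson limits with those equivalent counts
#' are then expressed through F quantiles:
#' lower = IRR / F(1 - a/2; 2(d0* + 1), 2 d1*) (d1* in the numerator role),
#' upper = IRR * F(1 - a/2; 2(d1* + 1), 2 d0*).
#'
#' @param asr1,asr0 one-row tibbles from [standardize()].
#' @param conf_level confidence level.
#' @return one-row tibble: `irr`, `ci_low`, `ci_high`, `method` (`"f_approx"`).
#' @export
irr_standardized <- function(asr1, asr0, conf_level = 0.95) {
  if (asr0$rate_per_100k <= 0) {
    abort("reference standardized rate is zero; ratio undefined",
          class = "carcmort_rate_error")
  }
  irr <- asr1$rate_per_100k / asr0$rate_per_100k
  d1s <- asr1$equiv_deaths
  d0s <- asr0$equiv_deaths
  a <- 1 - conf_level
  lo <- if (d1s <= 0) 0 else
    irr * d0s / (d0s + 1) / qf(1 - a / 2, 2 * (d0s + 1), 2 * d1s)
  hi <- if (d1s <= 0) Inf else
    irr * (d1s + 1) / d1s * qf(1 - a / 2, 2 * (d1s + 1), 2 * d0s)
  tibble(irr = irr, ci_low = lo, ci_high = hi, method = "f_approx")
}
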