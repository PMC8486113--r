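# Nonparametric smoothed hazard over exposure time: events and person-time
# are aggregated on a fine (monthly) grid and the log-hazard is smoothed by
# penalized B-spline Poisson regression with a person-time offset. Competing
# causes are treated as censoring, so the estimate is a cause-specific
# hazard.

#' Smoothed instantaneous event rate over exposure time
#'
#' @param time follow-up durations in years (from entry into the state).
#' @param event logical/0-1: event of the cause set at `time` (competing
#'   causes and administrative censoring are 0).
#' @param cause_set label carried into the result.
#' @param df smoothing control: `"penalized"` (default) estimates the
#'   smoothing parameter by REML with a first-order difference penalty and a
#'   dispersion estimate (the variance-components approach of standard
#'   hazard smoothers); `"aic"` selects a fixed df over `df_grid` by AIC; a
#'   number fixes the spline df directly. `df <= 2` fits the constant
#'   hazard (total events / total person-time).
#' @param df_grid candidate df values for AIC selection.
#' @param grid_dt grid resolution in years (default monthly).
#' @param conf_level level of the pointwise band (delta method on the log
#'   hazard).
#' @return object of class `carcmort_hazard`; see [tidy.carcmort_hazard()].
#' @export
smooth_hazard <- function(time, event, cause_set = "all", df = "penalized",
                          df_grid = c(3, 4, 5, 6, 8), grid_dt = 1 / 12,
                          conf_level = 0.95) {
  event <- as.logical(event)
  stopifnot(length(time) == length(event), all(time >= 0))
  n_events <- sum(event)
  if (n_events == 0) {
    abort("no events for this cause set; consider pooling causes",
          class = "carcmort_hazard_error")
  }
  tmax <- max(time)
  breaks <- seq(0, tmax + grid_dt, by = grid_dt)
  mids <- head(breaks, -1) + grid_dt / 2
  # person-time and events per grid interval (everyone enters at 0)
  py <- vapply(seq_along(mids), function(i) {
    sum(pmax(0, pmin(time, breaks[i + 1]) - breaks[i]))
  }, numeric(1))
  idx <- findInterval(time[event], breaks, rightmost.closed = TRUE)
  ev <- tabulate(idx, nbins = length(mids))
  dat <- tibble(t = mids, events = ev, py = py, log_py = log(py))
  dat <- filter(dat, .data$py > 0)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fit_one <- function(k_df) {
    # a cubic P-spline basis needs at least 4 coefficients; below that the
    # model degenerates to the constant hazard
    if (k_df <= 2 || nrow(dat) < k_df + 2) {
      g <- stats::glm(events ~ 1 + offset(log_py), family = stats::poisson,
                      data = dat)
    } else {
      g <- mgcv::gam(events ~ s(t, k = k_df + 1, fx = TRUE, bs = "ps") +
                       offset(log_py),
                     family = stats::poisson, data = dat, method = "REML")
    }
    g
  }
  if (identical(df, "penalized")) {
    k <- min(20, max(4, floor(nrow(dat) / 4)))
    g <- mgcv::gam(events ~ s(t, k = k, bs = "ps", m = c(2, 1)) +
                     offset(log_py),
                   family = stats::quasipoisson, data = dat,
                   method = "REML")
    df_used <- sum(g$edf)
  } else if (identical(df, "aic")) {
    fits <- lapply(df_grid, fit_one)
    aics <- vapply(fits, stats::AIC, numeric(1))
    best <- which.min(aics)
    g <- fits[[best]]
    df_used <- df_grid[best]
  } else {
    g <- fit_one(df)
    df_used <- df
  }
  nd <- tibble(t = dat$t, log_py = 0)
  pr <- stats::predict(g, newdata = nd, type = "link", se.fit = TRUE)
  curve <- tibble(time = dat$t,
                  hazard = exp(as.numeric(pr$fit)),
                  band_low = exp(as.numeric(pr$fit) - z * pr$se.fit),
                  band_high = exp(as.numeric(pr$fit) + z * pr$se.fit),
                  events = dat$events, person_years = dat$py)
  structure(list(curve = curve, cause_set = cause_set, df = df_used,
                 n_events = n_events, person_years = sum(dat$py),
                 aic = stats::AIC(g), conf_level = conf_level),
            class = "carcmort_hazard")
}

#' @export
print.carcmort_hazard <- function(x, ...) {
  cat(sprintf("<smoothed hazard: %s; %d events over %.0f person-years; df=%s>\n",
              x$cause_set, x$n_events, x$person_years, format(x$df)))
  invisible(x)
}

#' Tidy a smoothed hazard
#'
#' @param x `carcmort_hazard` object.
#' @param ... unused.
#' @return tibble `time`, `hazard`, `band_low`, `band_high`, `events`,
#'   `person_years` (hazard per person-year).
#' @export
tidy.carcmort_hazard <- function(x, ...) x$curve

#' One-row summary of a smoothed hazard
#' @param x `carcmort_hazard` object.
#' @param ... unused.
#' @return tibble with `cause_set`, `df`, `n_events`, `person_years`, `aic`.
#' @export
glance.carcmort_hazard <- function(x, ...) {
  tibble(cause_set = x$cause_set, df = x$df, n_events = x$n_events,
         person_years = x$person_years, aic = x$aic)
}

#' Plot a smoothed hazard curve
#'
#' @param object `carcmort_hazard`.
#' @param per scale of the y axis (events per `per` person-years).
#' @param ... unused.
#' @return ggplot object.
#' @export
autoplot.carcmort_hazard <- function(object, per = 1e5, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low * per,
                                      ymax = .data$band_high * per),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hazard * per)) +
    ggplot2::labs(x = "years of exposure",
                  y = sprintf("deaths per %s person-years",
                              format(per, big.mark = ",")),
                  title = sprintf("instantaneous mortality rate (%s)",
                                  object$cause_set)) +
    ggplot2::theme_minimal()
}
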