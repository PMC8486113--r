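# Kaplan-Meier survival, log-rank tests, and the reduced post-release cohort
# with consistent 5-year follow-up, stratified by cumulative incarceration.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (ties at identical times decrement
#' simultaneously), computed with the survival package.
#'
#' @param time follow-up durations (> 0).
#' @param event logical/0-1 event indicator.
#' @return tibble `time`, `n_risk`, `n_event`, `survival`, starting at
#'   `time = 0`, `survival = 1`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(all(time > 0))
  sf <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ 1)
  tibble(time = c(0, sf$time),
         n_risk = c(length(time), sf$n.risk),
         n_event = c(0, sf$n.event),
         survival = c(1, sf$surv))
}

#' Log-rank test across groups
#'
#' @param time,event as in [km_estimate()].
#' @param group group membership vector (>= 2 groups with events overall).
#' @return tibble `statistic`, `df`, `p_value`, `n_groups`.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  present <- table(group) > 0
  if (any(!present)) {
    warn(paste("dropping empty group(s):",
               paste(names(present)[!present], collapse = ", ")))
    group <- droplevels(group)
  }
  if (nlevels(group) < 2) abort("log-rank needs at least 2 non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(time, as.numeric(event)) ~ group)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         n_groups = length(sd$n))
}

#' Reduced post-release cohort with consistent follow-up
#'
#' Restricts to persons whose last release from prison precedes the window
#' end by at least `min_follow_years`, censors post-release follow-up at
#' `censor_years`, and attaches each person's cumulative time incarcerated
#' in any facility type prior to that release (summed over recorded
#' episodes).
#'
#' @param episodes episode tibble from [build_episodes()] (post-release
#'   episodes present).
#' @param deaths tibble `person_uid`, `death_date` and optionally
#'   `broad_cause`, for deaths to count as events.
#' @param study_window length-2 Date vector.
#' @param min_follow_years,censor_years reduced-cohort parameters (both 5 by
#'   default).
#' @param strata_breaks boundaries (years) for cumulative-incarceration
#'   strata.
#' @return tibble per person: `person_uid`, `release_date`,
#'   `cum_incarceration_years`, `incarceration_stratum`, `time` (years, in
#'   (0, censor_years]), `event`, `cause` (broad cause or NA).
#' @export
build_reduced_cohort <- function(episodes, deaths = NULL,
                                 study_window = as.Date(c("2009-01-01",
                                                          "2019-01-01")),
                                 min_follow_years = 5, censor_years = 5,
                                 strata_breaks = c(0, 0.5, 2, Inf)) {
  study_window <- as.Date(study_window)
  post <- episodes |>
    filter(.data$location == "post_release") |>
    group_by(.data$person_uid) |>
    summarise(release_date = max(.data$start), .groups = "drop") |>
    filter(interval_years(.data$release_date, study_window[2]) >=
             min_follow_years)
  if (nrow(post) == 0) return(tibble())
  cum_inc <- episodes |>
    filter(.data$location %in% FACILITY_TYPES) |>
    inner_join(post, by = "person_uid") |>
    filter(.data$start < .data$release_date) |>
    mutate(dur = interval_years(.data$start,
                                pmin(.data$end, .data$release_date))) |>
    group_by(.data$person_uid) |>
    summarise(cum_incarceration_years = sum(.data$dur), .groups = "drop")
  out <- post |>
    left_join(cum_inc, by = "person_uid") |>
    mutate(cum_incarceration_years =
             dplyr::coalesce(.data$cum_incarceration_years, 0))
  if (!is.null(deaths) && nrow(deaths) > 0) {
    dd <- deaths |>
      select("person_uid", "death_date",
             dplyr::any_of("broad_cause")) |>
      distinct(.data$person_uid, .keep_all = TRUE)
    out <- left_join(out, dd, by = "person_uid")
  } else {
    out$death_date <- as.Date(NA)
  }
  if (!"broad_cause" %in% names(out)) out$broad_cause <- NA_character_
  t_death <- interval_years(out$release_date, out$death_date)
  event <- !is.na(t_death) & t_death > 0 & t_death <= censor_years
  out$time <- ifelse(event, t_death, censor_years)
  out$event <- event
  out$cause <- ifelse(event, out$broad_cause, NA_character_)
  out$incarceration_stratum <- cut(out$cum_incarceration_years,
                                   breaks = strata_breaks,
                                   include.lowest = TRUE)
  select(out, "person_uid", "release_date", "cum_incarceration_years",
         "incarceration_stratum", "time", "event", "cause")
}
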