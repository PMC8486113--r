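# Conversion of per-person event sequences into censored exposure episodes.
# Facility episodes are censored at transfer to a different facility type,
# release, death, or the end of the study window; post-release episodes open
# at a release from prison (closed or semi-open by default) and are censored
# at reincarceration in any facility type, death, or the window end.
# Intervals are half-open [start, end): a transfer day counts toward the
# destination facility only.

#' Build censored exposure episodes from movement events
#'
#' @param events tibble with columns `person_uid`, `event_type` (arrest,
#'   transfer, release, death; other types are ignored), `facility_type`,
#'   `event_date`.
#' @param study_window length-2 Date vector (inclusive start, exclusive end);
#'   episodes are clipped to it.
#' @param release_from facility types whose release opens a post-release
#'   episode; default prison only. Use all four types to recompute the
#'   formerly-incarcerated person-time for denominator subtraction.
#' @return tibble of episodes: `person_uid`, `location`, `start`, `end`
#'   (Dates, half-open), `end_reason` (transfer, release, reincarceration,
#'   death, study_end). Episodes of one person never overlap.
#' @export
build_episodes <- function(events,
                           study_window = as.Date(c("2009-01-01", "2019-01-01")),
                           release_from = c("closed", "semi_open")) {
  study_window <- as.Date(study_window)
  events <- events |>
    filter(.data$event_type %in% c("arrest", "transfer", "release", "death")) |>
    mutate(.ord = match(.data$event_type,
                        c("arrest", "transfer", "release", "death"))) |>
    arrange(.data$person_uid, .data$event_date, .data$.ord)

  idx_by_person <- split(seq_len(nrow(events)), events$person_uid)
  n_guess <- nrow(events) + length(idx_by_person)
  o_pid <- character(n_guess); o_loc <- character(n_guess)
  o_st <- numeric(n_guess); o_en <- numeric(n_guess)
  o_why <- character(n_guess)
  m <- 0L
  ev_type <- events$event_type
  ev_date <- as.numeric(events$event_date)
  ev_fac <- events$facility_type
  w_end <- as.numeric(study_window[2])
  for (pid in names(idx_by_person)) {
    rows <- idx_by_person[[pid]]
    cur_loc <- NA_character_
    cur_start <- NA_real_
    dead <- FALSE
    for (i in rows) {
      if (dead) {
        abort(sprintf("events after death for person %s", pid),
              class = "carcmort_integrity_error")
      }
      type <- ev_type[i]; dt <- ev_date[i]; fac <- ev_fac[i]
      close_why <- NA_character_
      new_loc <- NA_character_
      if (type == "arrest" || type == "transfer") {
        close_why <- if (identical(cur_loc, "post_release"))
          "reincarceration" else "transfer"
        new_loc <- fac
      } else if (type == "release") {
        from <- if (!is.na(cur_loc) && cur_loc != "post_release") cur_loc
                else fac
        close_why <- "release"
        if (!is.na(from) && from %in% release_from) new_loc <- "post_release"
      } else if (type == "death") {
        close_why <- "death"
        dead <- TRUE
      }
      if (!is.na(cur_loc)) {
        m <- m + 1L
        o_pid[m] <- pid; o_loc[m] <- cur_loc; o_st[m] <- cur_start
        o_en[m] <- dt; o_why[m] <- close_why
      }
      cur_loc <- new_loc
      cur_start <- dt
    }
    if (!is.na(cur_loc)) {
      m <- m + 1L
      o_pid[m] <- pid; o_loc[m] <- cur_loc; o_st[m] <- cur_start
      o_en[m] <- w_end; o_why[m] <- "study_end"
    }
  }
  if (m == 0L) {
    return(tibble(person_uid = character(), location = character(),
                  start = as.Date(character()), end = as.Date(character()),
                  end_reason = character()))
  }
  tibble(person_uid = o_pid[seq_len(m)], location = o_loc[seq_len(m)],
         start = as.Date(o_st[seq_len(m)], origin = "1970-01-01"),
         end = as.Date(o_en[seq_len(m)], origin = "1970-01-01"),
         end_reason = o_why[seq_len(m)]) |>
    mutate(start = pmax(.data$start, study_window[1]),
           end = pmin(.data$end, study_window[2])) |>
    filter(.data$end > .data$start)
}

#' Truncate overlong episodes in under-reported facility types
#'
#' Release events are under-reported in police stations, semi-open prisons
#' and youth detention, leaving implausibly long recorded stays; such
#' episodes are shortened to a per-location cap with `end_reason`
#' "truncated". Closed-prison and post-release episodes are never truncated.
#'
#' @param episodes episode tibble from [build_episodes()].
#' @param caps named numeric vector of maximum durations in days.
#' @param quantile optional probability; when supplied, each capped
#'   location's cap is the empirical `quantile` of its episode durations
#'   (overriding `caps`).
#' @return episode tibble with affected rows shortened.
#' @export
truncate_overlong <- function(episodes,
                              caps = c(police = 30, semi_open = 730,
                                       youth = 1095),
                              quantile = NULL) {
  stopifnot(!"closed" %in% names(caps))
  if (!is.null(quantile)) {
    for (lc in names(caps)) {
      dur <- as.numeric(episodes$end - episodes$start)[episodes$location == lc]
      if (length(dur) > 0) {
        caps[lc] <- as.numeric(stats::quantile(dur, quantile, type = 1))
      }
    }
  }
  dur <- as.numeric(episodes$end - episodes$start)
  cap <- caps[episodes$location]
  hit <- !is.na(cap) & dur > cap
  episodes$end[hit] <- episodes$start[hit] + cap[hit]
  episodes$end_reason[hit] <- "truncated"
  episodes
}

#' Location at death of each person
#'
#' @param episodes episode tibble.
#' @return tibble `person_uid`, `location` for persons whose final episode
#'   ends in death; persons dying outside observation are absent.
#' @export
location_at_death <- function(episodes) {
  episodes |>
    filter(.data$end_reason == "death") |>
    select("person_uid", "location", death_date = "end")
}

#' Tabulate person-time from episodes
#'
#' Episode time is split exactly at calendar-year boundaries and, for
#' post-release episodes, at anniversaries of the release date, then summed
#' over the requested strata. Person-years use a 365.25-day year. Splitting
#' conserves totals exactly.
#'
#' @param episodes episode tibble.
#' @param persons optional tibble `person_uid`, `sex` used to stratify by sex.
#' @param by character vector of stratum columns among `location`, `sex`,
#'   `calendar_year`, `years_since_release`, `release_year`, `person_uid`.
#' @return tibble of the strata plus `person_years`.
#' @export
tabulate_person_time <- function(episodes, persons = NULL,
                                 by = c("location", "sex", "calendar_year")) {
  if (nrow(episodes) == 0) {
    out <- tibble(person_years = numeric(0))
    for (b in rev(by)) out <- bind_cols(tibble(!!b := character(0)), out)
    return(out)
  }
  segs <- split_episode_time(episodes)
  if (!is.null(persons)) {
    segs <- left_join(segs, select(persons, "person_uid", "sex"),
                      by = "person_uid")
  } else if ("sex" %in% by) {
    abort("`persons` must be supplied to stratify by sex")
  }
  segs |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(person_years = sum(.data$py), .groups = "drop")
}

# split episodes at calendar year boundaries and release anniversaries;
# returns one row per segment with exact fractional person-years
split_episode_time <- function(episodes) {
  ep <- episodes |>
    mutate(s = as.numeric(.data$start), e = as.numeric(.data$end),
           rel = as.numeric(.data$start))
  years <- seq(min(as.integer(format(episodes$start, "%Y"))),
               max(as.integer(format(episodes$end, "%Y"))))
  acc <- vector("list", length(years))
  for (j in seq_along(years)) {
    y0 <- as.numeric(as.Date(sprintf("%d-01-01", years[j])))
    y1 <- as.numeric(as.Date(sprintf("%d-01-01", years[j] + 1L)))
    s <- pmax(ep$s, y0); e <- pmin(ep$e, y1)
    keep <- e > s
    if (!any(keep)) next
    acc[[j]] <- tibble(person_uid = ep$person_uid[keep],
                       location = ep$location[keep],
                       calendar_year = years[j],
                       rel = ep$rel[keep],
                       release_year = as.integer(format(episodes$start[keep], "%Y")),
                       s = s[keep], e = e[keep])
  }
  segs <- bind_rows(acc)
  # post-release anniversary split (year 0, 1, 2, ... since release)
  post <- segs$location == "post_release"
  out <- segs[!post, ]
  out$years_since_release <- NA_integer_
  out$py <- (out$e - out$s) / DAYS_PER_YEAR
  out$release_year <- NA_integer_
  if (any(post)) {
    ps <- segs[post, ]
    kmax <- max(ceiling((ps$e - ps$rel) / DAYS_PER_YEAR))
    acc2 <- vector("list", kmax)
    for (k in seq_len(kmax) - 1L) {
      b0 <- ps$rel + k * DAYS_PER_YEAR
      b1 <- ps$rel + (k + 1) * DAYS_PER_YEAR
      s <- pmax(ps$s, b0); e <- pmin(ps$e, b1)
      keep <- e > s
      if (!any(keep)) next
      seg <- ps[keep, ]
      seg$years_since_release <- k
      seg$py <- (e[keep] - s[keep]) / DAYS_PER_YEAR
      acc2[[k + 1L]] <- seg
    }
    out <- bind_rows(out, bind_rows(acc2))
  }
  select(out, "person_uid", "location", "calendar_year", "release_year",
         "years_since_release", "py")
}
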