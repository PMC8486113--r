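wnd <- as.Date(c("2009-01-01", "2019-01-01"))

mkev <- function(...) {
  rows <- list(...)
  tibble::tibble(
    person_uid = vapply(rows, `[[`, "", 1),
    event_type = vapply(rows, `[[`, "", 2),
    facility_type = vapply(rows, function(r) r[[3]], FUN.VALUE = ""),
    event_date = as.Date(vapply(rows, `[[`, "", 4)))
}

test_that("a single custody cycle yields one facility and one open post-release episode", {
  ev <- mkev(c("P1", "arrest", "closed", "2010-01-01"),
             c("P1", "release", "closed", "2010-07-01"))
  ep <- build_episodes(ev, wnd)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$location, c("closed", "post_release"))
  expect_equal(as.numeric(ep$end[1] - ep$start[1]), 181)
  expect_equal(ep$end_reason, c("release", "study_end"))
  expect_equal(ep$end[2], wnd[2])
})

test_that("transfer and death censor episodes with the right reasons", {
  ev <- mkev(c("P1", "arrest", "closed", "2010-01-01"),
             c("P1", "transfer", "semi_open", "2010-03-01"),
             c("P1", "death", NA, "2010-05-01"))
  ep <- build_episodes(ev, wnd)
  expect_equal(ep$location, c("closed", "semi_open"))
  expect_equal(ep$end_reason, c("transfer", "death"))
})

test_that("post-release only opens after release from prison", {
  ev <- mkev(c("P1", "arrest", "police", "2010-01-01"),
             c("P1", "release", "police", "2010-01-10"))
  ep <- build_episodes(ev, wnd)
  expect_equal(ep$location, "police")
  ep2 <- build_episodes(ev, wnd, release_from = c("closed", "semi_open",
                                                  "police", "youth"))
  expect_equal(ep2$location, c("police", "post_release"))
})

test_that("post-release ends at reincarceration", {
  ev <- mkev(c("P1", "arrest", "closed", "2010-01-01"),
             c("P1", "release", "closed", "2011-01-01"),
             c("P1", "arrest", "police", "2012-01-01"))
  ep <- build_episodes(ev, wnd)
  expect_equal(ep$location, c("closed", "post_release", "police"))
  expect_equal(ep$end_reason[2], "reincarceration")
})

test_that("events after a death are an integrity error naming the person", {
  ev <- mkev(c("P9", "death", NA, "2010-01-01"),
             c("P9", "arrest", "closed", "2011-01-01"))
  expect_error(build_episodes(ev, wnd), "P9",
               class = "carcmort_integrity_error")
})

test_that("episode time agrees with an independent per-person walk", {
  coh <- clean_cohort()
  ev <- truth_events(coh)
  ep <- build_episodes(ev, wnd)
  got <- ep |>
    dplyr::group_by(person_uid, location) |>
    dplyr::summarise(days = sum(as.numeric(end - start)), .groups = "drop")
  # oracle: brute-force state walk over each person's dated events
  ref <- list()
  for (pid in unique(ev$person_uid)) {
    e <- ev[ev$person_uid == pid, ]
    e <- e[order(e$event_date,
                 match(e$event_type,
                       c("arrest", "transfer", "release", "death"))), ]
    state <- NA_character_; since <- as.Date(NA)
    push <- function(to) {
      if (!is.na(state)) {
        ref[[length(ref) + 1]] <<- data.frame(
          person_uid = pid, location = state,
          days = as.numeric(to - since))
      }
    }
    for (i in seq_len(nrow(e))) {
      t <- e$event_type[i]; d <- e$event_date[i]
      if (t %in% c("arrest", "transfer")) {
        push(d); state <- e$facility_type[i]; since <- d
      } else if (t == "release") {
        from <- state; push(d)
        if (!is.na(from) && from %in% c("closed", "semi_open")) {
          state <- "post_release"; since <- d
        } else state <- NA_character_
      } else if (t == "death") {
        push(d); state <- NA_character_
      }
    }
    push(wnd[2])
  }
  ref <- dplyr::bind_rows(ref) |>
    dplyr::group_by(person_uid, location) |>
    dplyr::summarise(days = sum(days), .groups = "drop") |>
    dplyr::filter(days > 0)
  merged <- dplyr::full_join(got, ref, by = c("person_uid", "location"),
                             suffix = c("_got", "_ref"))
  expect_true(all(!is.na(merged$days_got) & !is.na(merged$days_ref)))
  expect_equal(merged$days_got, merged$days_ref)
})

test_that("truncation caps shorten only the targeted locations", {
  ep <- tibble::tibble(
    person_uid = c("A", "B", "C"),
    location = c("police", "closed", "police"),
    start = as.Date(c("2010-01-01", "2010-01-01", "2010-01-01")),
    end = as.Date(c("2011-02-05", "2012-01-01", "2010-01-15")),
    end_reason = "release")
  out <- truncate_overlong(ep, caps = c(police = 30))
  expect_equal(as.numeric(out$end[1] - out$start[1]), 30)
  expect_equal(out$end_reason[1], "truncated")
  expect_equal(out$end[2], ep$end[2])     # closed never truncated
  expect_equal(out$end[3], ep$end[3])     # under the cap: untouched
  expect_identical(truncate_overlong(ep, caps = c(police = 5000)), ep)
})

test_that("quantile-rule truncation matches a brute-force count", {
  coh <- clean_cohort()
  ep <- build_episodes(truth_events(coh), wnd)
  out <- truncate_overlong(ep, caps = c(police = NA), quantile = 0.95)
  dur <- as.numeric(ep$end - ep$start)[ep$location == "police"]
  cap <- as.numeric(stats::quantile(dur, 0.95, type = 1))
  expect_equal(sum(out$end_reason == "truncated"), sum(dur > cap))
})

test_that("person-years use the 365.25-day year", {
  ep <- tibble::tibble(person_uid = "A", location = "closed",
                       start = as.Date("2010-01-01"),
                       end = as.Date("2010-01-01") + 1461,
                       end_reason = "release")
  pt <- tabulate_person_time(ep, by = "location")
  expect_equal(pt$person_years, 1461 / 365.25)
  expect_equal(days_to_years(365.25), 1.0)
})

test_that("calendar-year splitting is exact day-count arithmetic", {
  ep <- tibble::tibble(person_uid = "A", location = "closed",
                       start = as.Date("2012-07-01"),
                       end = as.Date("2013-07-01"),
                       end_reason = "release")
  pt <- tabulate_person_time(ep, by = c("location", "calendar_year"))
  expect_equal(sort(pt$calendar_year), c(2012, 2013))
  expect_equal(pt$person_years[pt$calendar_year == 2012], 184 / 365.25)
  expect_equal(pt$person_years[pt$calendar_year == 2013], 181 / 365.25)
  expect_equal(sum(pt$person_years), 365 / 365.25)
})

test_that("splitting and stratification conserve totals exactly", {
  coh <- clean_cohort()
  ep <- build_episodes(truth_events(coh), wnd)
  persons <- coh$truth$persons[, c("person_uid", "sex")]
  total <- sum(as.numeric(ep$end - ep$start)) / 365.25
  pt1 <- tabulate_person_time(ep, persons,
                              by = c("location", "sex", "calendar_year"))
  expect_equal(sum(pt1$person_years), total, tolerance = 1e-9)
  post <- ep[ep$location == "post_release", ]
  pt2 <- tabulate_person_time(post, persons,
                              by = c("sex", "release_year",
                                     "years_since_release"))
  expect_equal(sum(pt2$person_years),
               sum(as.numeric(post$end - post$start)) / 365.25,
               tolerance = 1e-9)
  # facility components sum to total custody person-time
  cust <- pt1[pt1$location %in% c("closed", "semi_open", "police", "youth"), ]
  cust_total <- sum(as.numeric(ep$end - ep$start)[
    ep$location %in% c("closed", "semi_open", "police", "youth")]) / 365.25
  expect_equal(sum(cust$person_years), cust_total, tolerance = 1e-9)
})

test_that("no person exceeds the window length across all populations", {
  coh <- noisy_cohort()
  ep <- build_episodes(truth_events(coh), wnd)
  per <- ep |>
    dplyr::group_by(person_uid) |>
    dplyr::summarise(py = sum(as.numeric(end - start)) / 365.25)
  expect_true(all(per$py <= as.numeric(diff(wnd)) / 365.25 + 1e-9))
})
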