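# Vectorized continuous-time Markov simulation of carceral careers with a
# competing mortality clock. States: free_never, closed, semi_open, police,
# youth, post_release (from prison), free_other (released from police/youth).
# All rates are piecewise constant in age (mortality bands), state, and -- for
# post-release -- integer year since release, so the event-driven simulation
# below is exact: each person either fires an exponential event or advances
# deterministically to the next rate-change boundary.

ST_FREE <- 1L; ST_CLOSED <- 2L; ST_SEMI <- 3L; ST_POLICE <- 4L
ST_YOUTH <- 5L; ST_POST <- 6L; ST_FREEOTHER <- 7L
STATE_CODES <- c("free_never", "closed", "semi_open", "police", "youth",
                 "post_release", "free_other")

# step-function lookup of baseline mortality (per person-year) by sex and age
baseline_lookup <- function(baseline_mortality) {
  make_one <- function(sx) {
    tab <- arrange(filter(baseline_mortality, .data$sex == sx), .data$age_low)
    list(breaks = tab$age_low, rates = tab$rate_100k / 1e5,
         top = max(tab$age_high))
  }
  list(male = make_one("male"), female = make_one("female"))
}

base_rate_at <- function(lk, sex_int, age) {
  out <- numeric(length(age))
  for (s in 1:2) {
    sel <- sex_int == s
    if (!any(sel)) next
    tb <- if (s == 1L) lk$male else lk$female
    idx <- findInterval(pmin(age[sel], tb$top), tb$breaks)
    idx[idx < 1L] <- 1L
    out[sel] <- tb$rates[idx]
  }
  out
}

# next mortality-band boundary strictly above the current age
next_band_delta <- function(lk, sex_int, age) {
  out <- rep(Inf, length(age))
  for (s in 1:2) {
    sel <- sex_int == s
    if (!any(sel)) next
    tb <- if (s == 1L) lk$male else lk$female
    a <- age[sel]
    idx <- findInterval(a, tb$breaks) + 1L
    nb <- rep(Inf, length(a))
    ok <- idx <= length(tb$breaks)
    nb[ok] <- tb$breaks[idx[ok]] - a[ok]
    out[sel] <- nb
  }
  out
}

# Core engine. Returns events (including deaths) as a tibble ordered by
# person and time. `baseline` may be NULL for a pure career simulation.
run_careers <- function(age0, sex, window_years, career_rates,
                        baseline = NULL,
                        state_rate_ratios = default_state_rate_ratios(),
                        postrelease_decay = 1.0, adult_age = 18) {
  n <- length(age0)
  stopifnot(length(sex) == n)
  if (n == 0) {
    return(tibble(person = integer(), time = numeric(), kind = character(),
                  facility = character(), state_after = character()))
  }
  cr <- career_rates
  rr <- state_rate_ratios[STATE_CODES]
  lk <- if (is.null(baseline)) NULL else baseline_lookup(baseline)
  sex_int <- ifelse(sex == "male", 1L, 2L)
  decay <- as.numeric(postrelease_decay)

  t <- numeric(n)
  state <- rep(ST_FREE, n)
  release_time <- rep(NA_real_, n)
  active <- rep(TRUE, n)

  trans_out <- c(0,
                 cr$release[["closed"]] + cr$transfer[["closed_to_semi_open"]],
                 cr$release[["semi_open"]] + cr$transfer[["semi_open_to_closed"]],
                 cr$release[["police"]] + cr$transfer[["police_to_closed"]],
                 cr$release[["youth"]],
                 cr$reincarceration[["post_release"]],
                 cr$reincarceration[["free_other"]])

  acc_p <- integer(0); acc_t <- numeric(0); acc_k <- character(0)
  acc_f <- character(0); acc_s <- character(0)
  push <- function(person, time, kind, facility, state_after) {
    acc_p <<- c(acc_p, person); acc_t <<- c(acc_t, time)
    acc_k <<- c(acc_k, kind); acc_f <<- c(acc_f, facility)
    acc_s <<- c(acc_s, state_after)
  }
  entry_fac <- function(k, minor) {
    # admission facility: minors go to youth detention, adults per entry_mix
    fac <- integer(k)
    fac[minor] <- ST_YOUTH
    na <- sum(!minor)
    if (na > 0) {
      mix <- cr$entry_mix[c("closed", "semi_open", "police")]
      fac[!minor] <- sample(c(ST_CLOSED, ST_SEMI, ST_POLICE), na,
                            replace = TRUE, prob = mix)
    }
    fac
  }

  guard <- 0L
  while (any(active)) {
    guard <- guard + 1L
    if (guard > 100000L) abort("career simulation failed to terminate")
    idx <- which(active)
    st <- state[idx]
    age <- age0[idx] + t[idx]
    minor <- age < adult_age

    tr <- trans_out[st]
    free_sel <- st == ST_FREE
    tr[free_sel] <- ifelse(minor[free_sel], cr$minor_arrest, cr$arrest)

    if (is.null(lk)) {
      dr <- numeric(length(idx))
    } else {
      dmult <- rr[st]
      post_sel <- st == ST_POST
      if (any(post_sel)) {
        tsr <- t[idx][post_sel] - release_time[idx][post_sel]
        di <- pmin(floor(tsr) + 1L, length(decay))
        dmult[post_sel] <- dmult[post_sel] * decay[di]
      }
      dr <- base_rate_at(lk, sex_int[idx], age) * dmult
    }
    total <- tr + dr

    d_window <- window_years - t[idx]
    d_band <- if (is.null(lk)) rep(Inf, length(idx)) else
      next_band_delta(lk, sex_int[idx], age)
    d_adult <- ifelse(minor, adult_age - age, Inf)
    d_tsr <- rep(Inf, length(idx))
    if (length(decay) > 1) {
      post_sel <- st == ST_POST
      if (any(post_sel)) {
        tsr <- t[idx][post_sel] - release_time[idx][post_sel]
        d_tsr[post_sel] <- floor(tsr) + 1 - tsr
      }
    }
    d_bound <- pmin(d_window, d_band, d_adult, d_tsr) + 1e-12

    dt <- rep(Inf, length(idx))
    pos <- total > 0
    dt[pos] <- rexp(sum(pos)) / total[pos]

    fires <- dt < d_bound
    # --- advance non-firing persons to their boundary
    adv <- idx[!fires]
    if (length(adv) > 0) {
      t[adv] <- t[adv] + d_bound[!fires]
      hit_window <- t[adv] >= window_years - 1e-12
      done <- adv[hit_window]
      active[done] <- FALSE
      # youth detainees reaching adulthood move to closed prison
      still <- adv[!hit_window]
      if (length(still) > 0) {
        aged_out <- still[state[still] == ST_YOUTH &
                            (age0[still] + t[still]) >= adult_age - 1e-9]
        if (length(aged_out) > 0) {
          state[aged_out] <- ST_CLOSED
          push(aged_out, t[aged_out], rep("transfer", length(aged_out)),
               rep("closed", length(aged_out)),
               rep("closed", length(aged_out)))
        }
      }
    }
    # --- resolve fired events
    frs <- idx[fires]
    if (length(frs) > 0) {
      te <- t[frs] + dt[fires]
      t[frs] <- te
      u <- runif(length(frs)) * total[fires]
      is_death <- u < dr[fires]
      dd <- frs[is_death]
      if (length(dd) > 0) {
        in_fac <- state[dd] %in% c(ST_CLOSED, ST_SEMI, ST_POLICE, ST_YOUTH)
        push(dd, t[dd], rep("death", length(dd)),
             ifelse(in_fac, STATE_CODES[state[dd]], NA_character_),
             rep(NA_character_, length(dd)))
        active[dd] <- FALSE
      }
      mv <- frs[!is_death]
      if (length(mv) > 0) {
        stm <- state[mv]
        agem <- age0[mv] + t[mv]
        # admissions from any free state
        adm <- mv[stm %in% c(ST_FREE, ST_POST, ST_FREEOTHER)]
        if (length(adm) > 0) {
          fac <- entry_fac(length(adm), (age0[adm] + t[adm]) < adult_age)
          state[adm] <- fac
          push(adm, t[adm], rep("arrest", length(adm)),
               STATE_CODES[fac], STATE_CODES[fac])
        }
        # custody exits: release vs transfer, proportional to intensities
        for (stc in c(ST_CLOSED, ST_SEMI, ST_POLICE, ST_YOUTH)) {
          cur <- mv[stm == stc]
          if (length(cur) == 0) next
          rel_rate <- cr$release[[STATE_CODES[stc]]]
          tr_rate <- switch(STATE_CODES[stc],
                            closed = cr$transfer[["closed_to_semi_open"]],
                            semi_open = cr$transfer[["semi_open_to_closed"]],
                            police = cr$transfer[["police_to_closed"]],
                            youth = 0)
          relsd <- runif(length(cur)) < rel_rate / (rel_rate + tr_rate)
          rel <- cur[relsd]
          if (length(rel) > 0) {
            from_prison <- stc %in% c(ST_CLOSED, ST_SEMI)
            state[rel] <- if (from_prison) ST_POST else ST_FREEOTHER
            if (from_prison) release_time[rel] <- t[rel]
            push(rel, t[rel], rep("release", length(rel)),
                 rep(STATE_CODES[stc], length(rel)),
                 rep(STATE_CODES[if (from_prison) ST_POST else ST_FREEOTHER],
                     length(rel)))
          }
          trf <- cur[!relsd]
          if (length(trf) > 0) {
            dest <- switch(STATE_CODES[stc], closed = ST_SEMI,
                           semi_open = ST_CLOSED, police = ST_CLOSED,
                           youth = ST_CLOSED)
            state[trf] <- dest
            push(trf, t[trf], rep("transfer", length(trf)),
                 rep(STATE_CODES[dest], length(trf)),
                 rep(STATE_CODES[dest], length(trf)))
          }
        }
      }
    }
  }
  if (length(acc_p) == 0) {
    return(tibble(person = integer(), time = numeric(), kind = character(),
                  facility = character(), state_after = character()))
  }
  arrange(tibble(person = acc_p, time = acc_t, kind = acc_k,
                 facility = acc_f, state_after = acc_s),
          .data$person, .data$time)
}

#' Simulate carceral careers for a set of individuals
#'
#' Runs the continuous-time Markov career model for `length(age)` persons
#' over a window of `window_years`, optionally with the competing mortality
#' clock. Events are time-ordered within person; a death, if present, is the
#' terminal event; youth-detention admission only occurs below `adult_age`.
#'
#' @param age numeric ages at window start.
#' @param sex `"male"`/`"female"`, recycled to `length(age)`.
#' @param career_rates list as from [default_career_rates()].
#' @param window_years length of the observation window in years.
#' @param baseline_mortality baseline schedule as from
#'   [default_baseline_mortality()], or `NULL` to disable mortality.
#' @param state_rate_ratios,postrelease_decay,adult_age see
#'   [synthetic_config()].
#' @param seed optional integer seed.
#' @return tibble with columns `person`, `time` (years since window start),
#'   `kind` (arrest/transfer/release/death), `facility`, `state_after`.
#' @export
simulate_career <- function(age, sex = "male",
                            career_rates = default_career_rates(),
                            window_years = 10,
                            baseline_mortality = NULL,
                            state_rate_ratios = default_state_rate_ratios(),
                            postrelease_decay = 1.0,
                            adult_age = 18, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_rate(window_years, "window_years")
  sex <- rep_len(sex, length(age))
  run_careers(age, sex, window_years, career_rates, baseline_mortality,
              state_rate_ratios, postrelease_decay, adult_age)
}

#' Generate a synthetic movement log, mortality registry, and ground truth
#'
#' Simulates `n_individuals` residents over the study window under the
#' configured career and mortality model, then renders (a) a movement log in
#' the style of a state incarceration database (one row per arrest, transfer,
#' release, or in-custody death, with internal IDs, noisy names, facility and
#' date), (b) a mortality registry (one row per death, with noisy names, sex,
#' date, age and an ICD-10 underlying cause), and (c) a truth object linking
#' every generated row to its generating individual.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with elements `movements`, `deaths`, `truth` (list of
#'   `persons`, `rows`, `episodes`), `age_tables` (list of `incarcerated` and
#'   `population` binned tables), and `config`.
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "carcmort_config"))
  set.seed(seed)
  n <- config$n_individuals
  w0 <- config$study_window[1]
  wy <- interval_years(config$study_window[1], config$study_window[2])

  if (n == 0) {
    empty_truth <- list(
      persons = tibble(person_uid = character(), sex = character(),
                       age_start = numeric(), name = character(),
                       mother_name = character(), died = logical(),
                       death_time = numeric(),
                       true_status_at_death = character(),
                       true_cause = character(),
                       true_age_at_death = numeric()),
      rows = tibble(row_id = character(), table = character(),
                    person_uid = character()),
      episodes = tibble(person_uid = character(), state = character(),
                        start = numeric(), end = numeric()))
    return(list(movements = empty_movement_log(), deaths = empty_death_registry(),
                truth = empty_truth, age_tables = NULL, config = config))
  }

  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  minor <- runif(n) < config$minor_fraction
  age0 <- numeric(n)
  age0[minor] <- runif(sum(minor), 14, config$adult_age)
  for (sx in c("male", "female")) {
    sel <- !minor & sex == sx
    if (!any(sel)) next
    tab <- arrange(config$age_binned_target[[sx]], .data$age_low)
    bin <- sample.int(nrow(tab), sum(sel), replace = TRUE, prob = tab$proportion)
    age0[sel] <- runif(sum(sel), tab$age_low[bin], tab$age_high[bin] + 1)
  }
  person_uid <- sprintf("P%06d", seq_len(n))
  nm <- draw_person_names(sex)

  events <- run_careers(age0, sex, wy, config$career_rates,
                        config$baseline_mortality, config$state_rate_ratios,
                        config$postrelease_decay, config$adult_age)

  # --- deaths and causes
  dth <- filter(events, .data$kind == "death")
  died <- rep(FALSE, n); died[dth$person] <- TRUE
  death_time <- rep(NA_real_, n); death_time[dth$person] <- dth$time
  status_at_death <- rep(NA_character_, n)
  # state at death: facility if in custody, else reconstruct from last event
  state_at_death <- state_at_time(events, dth$person, dth$time)
  status_at_death[dth$person] <- state_at_death
  cause <- rep(NA_character_, n)
  if (nrow(dth) > 0) {
    mixes <- config$cause_mix
    for (stt in unique(state_at_death)) {
      sel <- dth$person[state_at_death == stt]
      p <- as.numeric(mixes[mixes$state == stt, BROAD_CAUSES])
      cause[sel] <- sample(BROAD_CAUSES, length(sel), replace = TRUE, prob = p)
    }
  }

  truth_persons <- tibble(
    person_uid = person_uid, sex = sex, age_start = age0,
    name = nm$name, mother_name = nm$mother_name, died = died,
    death_time = death_time,
    true_status_at_death = if_else(died, status_at_death, "alive"),
    true_cause = cause,
    true_age_at_death = if_else(died, age0 + death_time, NA_real_))

  # --- movement log rendering
  log_ev <- filter(events, .data$kind != "death")
  if (config$custody_death_logged_prob > 0 && nrow(dth) > 0) {
    in_custody <- state_at_death %in% FACILITY_TYPES
    logged <- in_custody & runif(nrow(dth)) < config$custody_death_logged_prob
    log_ev <- bind_rows(log_ev, dth[logged, ])
  }
  log_ev <- arrange(log_ev, .data$person, .data$time)
  movements <- render_movement_log(log_ev, truth_persons, config, w0, wy)

  # --- mortality registry rendering
  deaths <- render_death_registry(dth, state_at_death, cause, truth_persons,
                                  config, w0)

  truth_rows <- bind_rows(
    tibble(row_id = movements$row_id, table = "movement",
           person_uid = movements$.person_uid),
    tibble(row_id = deaths$row_id, table = "death",
           person_uid = deaths$.person_uid))
  movements$.person_uid <- NULL
  deaths$.person_uid <- NULL

  truth_episodes <- events_to_truth_episodes(events, person_uid, wy)
  age_tables <- realized_age_tables(truth_persons, truth_episodes, config)

  list(movements = movements, deaths = deaths,
       truth = list(persons = truth_persons, rows = truth_rows,
                    episodes = truth_episodes),
       age_tables = age_tables, config = config)
}

empty_movement_log <- function() {
  tibble(row_id = character(), internal_id = character(), name = character(),
         mother_name = character(), sex = character(),
         event_type = character(),
         facility_type = character(), event_date = as.Date(character()))
}

empty_death_registry <- function() {
  tibble(row_id = character(), name = character(), mother_name = character(),
         sex = character(), death_date = as.Date(character()),
         age_at_death = numeric(), icd10_code = character())
}

# occupancy state (label) of each person at their death, from the event
# stream: the state_after of the last non-death event preceding the death
state_at_time <- function(events, persons, times) {
  if (length(persons) == 0) return(character(0))
  ev <- events |>
    group_by(.data$person) |>
    mutate(prior_state = dplyr::lag(.data$state_after,
                                    default = "free_never")) |>
    ungroup() |>
    filter(.data$kind == "death")
  ev$prior_state[match(persons, ev$person)]
}

events_to_truth_episodes <- function(events, person_uid, wy) {
  # persons without any event spend the whole window never incarcerated
  no_event <- setdiff(seq_along(person_uid),
                      if (nrow(events)) unique(events$person) else integer(0))
  base <- tibble(person_uid = person_uid[no_event], state = "free_never",
                 start = 0, end = wy)
  if (nrow(events) == 0) return(base)
  ev <- events |>
    group_by(.data$person) |>
    mutate(next_t = dplyr::lead(.data$time),
           first = dplyr::row_number() == 1L) |>
    ungroup()
  firsts <- filter(ev, .data$first)
  init <- tibble(person_uid = person_uid[firsts$person],
                 state = "free_never", start = 0, end = firsts$time)
  segs <- ev |>
    filter(.data$kind != "death") |>
    mutate(end = if_else(is.na(.data$next_t), wy, .data$next_t))
  segs <- tibble(person_uid = person_uid[segs$person],
                 state = segs$state_after, start = segs$time,
                 end = segs$end)
  bind_rows(base, init, segs) |>
    filter(.data$end > .data$start + 1e-12) |>
    arrange(.data$person_uid, .data$start)
}

render_movement_log <- function(log_ev, persons, config, w0, wy) {
  if (nrow(log_ev) == 0) {
    out <- empty_movement_log()
    out$.person_uid <- character()
    return(out)
  }
  p <- log_ev$person
  rgi <- sprintf("R%06d", p)
  # a slice of individuals carries a second internal ID for later events
  dup_person <- which(runif(nrow(persons)) < config$duplicate_id_prob)
  if (length(dup_person) > 0) {
    cut <- runif(length(dup_person), 0, wy)
    names(cut) <- as.character(dup_person)
    sel <- p %in% dup_person
    use2 <- sel
    use2[sel] <- log_ev$time[sel] > cut[as.character(p[sel])]
    rgi[use2] <- sprintf("R%06d", p[use2] + nrow(persons))
  }
  noise <- config$name_noise
  name <- perturb_string(persons$name[p], noise)
  mother <- persons$mother_name[p]
  miss <- runif(length(mother)) < noise$missing_mother
  mother_out <- ifelse(miss, NA_character_, perturb_string(mother, noise))
  tibble(
    row_id = sprintf("M%07d", seq_len(nrow(log_ev))),
    internal_id = rgi,
    name = name,
    mother_name = mother_out,
    sex = persons$sex[p],   # as inferred upstream from facility information
    event_type = log_ev$kind,
    facility_type = log_ev$facility,
    event_date = w0 + floor(years_to_days(log_ev$time)),
    .person_uid = sprintf("P%06d", p))
}

render_death_registry <- function(dth, state_at_death, cause_all, persons,
                                  config, w0) {
  if (nrow(dth) == 0) {
    out <- empty_death_registry()
    out$.person_uid <- character()
    return(out)
  }
  keep <- runif(nrow(dth)) >= config$registry_missing_prob
  dth <- dth[keep, ]
  stt <- state_at_death[keep]
  p <- dth$person
  cause <- cause_all[p]
  noise <- config$name_noise
  icd <- sample_icd(cause)
  in_custody <- stt %in% FACILITY_TYPES
  y20 <- in_custody & persons$sex[p] == "male" &
    cause %in% c("violence", "suicide") &
    runif(length(p)) < config$y20_misreport_prob
  icd[y20] <- "Y20"
  age_at_death <- persons$age_start[p] + dth$time
  miss_age <- runif(length(p)) < config$age_missing_prob
  mother <- persons$mother_name[p]
  miss_m <- runif(length(p)) < noise$missing_mother
  tibble(
    row_id = sprintf("D%06d", seq_along(p)),
    name = perturb_string(persons$name[p], noise),
    mother_name = ifelse(miss_m, NA_character_,
                         perturb_string(mother, noise)),
    sex = persons$sex[p],
    death_date = w0 + floor(years_to_days(dth$time)),
    age_at_death = ifelse(miss_age, NA_real_, floor(age_at_death)),
    icd10_code = icd,
    .person_uid = sprintf("P%06d", p))
}

# Binned age tables realized by the simulation, in the shape administrative
# aggregates are published: adult custody structure per sex-year (closed,
# semi-open and police pooled; youth detention has no age table), and the
# whole-population structure per sex-year with absolute person-years.
realized_age_tables <- function(persons, episodes, config) {
  w0 <- config$study_window[1]
  y0 <- as.integer(format(w0, "%Y"))
  wy <- as.integer(format(config$study_window[2] - 1, "%Y")) - y0 + 1L
  adult_bins <- arrange(config$age_binned_target$male, .data$age_low)
  # population structure in the 5-year bins demographic projections publish
  pop_breaks <- c(14, seq(20, 90, 5))
  pop_tops <- c(19, seq(24, 89, 5), 95)

  age_start <- setNames(persons$age_start, persons$person_uid)
  sex_of <- setNames(persons$sex, persons$person_uid)

  inc <- filter(episodes, .data$state %in% c("closed", "semi_open", "police"))
  inc_tab <- purrr::map_dfr(0:(wy - 1), function(y) {
    seg <- inc |>
      mutate(s = pmax(.data$start, y), e = pmin(.data$end, y + 1)) |>
      filter(.data$e > .data$s) |>
      mutate(py = .data$e - .data$s,
             age = age_start[.data$person_uid] + (.data$s + .data$e) / 2,
             sex = sex_of[.data$person_uid]) |>
      filter(.data$age >= 18)
    if (nrow(seg) == 0) return(NULL)
    seg$bin <- findInterval(pmin(seg$age, max(adult_bins$age_high)),
                            adult_bins$age_low)
    seg |>
      group_by(.data$sex, .data$bin) |>
      summarise(py = sum(.data$py), .groups = "drop") |>
      group_by(.data$sex) |>
      mutate(proportion = .data$py / sum(.data$py),
             year = y0 + y,
             age_low = adult_bins$age_low[.data$bin],
             age_high = adult_bins$age_high[.data$bin]) |>
      ungroup() |>
      select("sex", "year", "age_low", "age_high", "proportion")
  })

  alive_until <- if_else(persons$died, persons$death_time,
                         interval_years(config$study_window[1],
                                        config$study_window[2]))
  pop_tab <- purrr::map_dfr(0:(wy - 1), function(y) {
    py <- pmax(0, pmin(alive_until, y + 1) - y)
    mid_age <- persons$age_start + y + 0.5
    keep <- py > 0
    df <- tibble(sex = persons$sex[keep],
                 bin = findInterval(pmin(mid_age[keep], 95), pop_breaks),
                 py = py[keep])
    df |>
      group_by(.data$sex, .data$bin) |>
      summarise(person_years = sum(.data$py), .groups = "drop") |>
      mutate(year = y0 + y,
             age_low = pop_breaks[.data$bin],
             age_high = pop_tops[.data$bin]) |>
      group_by(.data$sex) |>
      mutate(proportion = .data$person_years / sum(.data$person_years)) |>
      ungroup() |>
      select("sex", "year", "age_low", "age_high", "proportion",
             "person_years")
  })
  list(incarcerated = inc_tab, population = pop_tab)
}

#' Sample plausible ICD-10 underlying-cause codes for broad cause categories
#'
#' @param broad character vector of broad cause labels.
#' @return character vector of ICD-10 codes.
#' @keywords internal
sample_icd <- function(broad) {
  vapply(broad, function(b) {
    inter <- sample(names(INTERMEDIATE_MIX[[b]]), 1L,
                    prob = INTERMEDIATE_MIX[[b]])
    sample(ICD_EXAMPLES[[inter]], 1L)
  }, character(1), USE.NAMES = FALSE)
}
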