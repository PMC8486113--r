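# End-to-end orchestration: registries in, mortality estimates out. Stages:
# deduplicate the movement log, link deaths, build censored episodes,
# tabulate person-time, disaggregate age structure, classify causes, compute
# standardized rates and rate ratios, smooth post-release hazards, and run
# the reduced-cohort survival analysis. Every filter step is counted in a
# run manifest so the headline accounting identities can be reproduced from
# the manifest alone.

#' Run the full mortality pipeline
#'
#' @param config a [synthetic_config()]; used to generate data when `data`
#'   is not supplied, and for the study window.
#' @param seed integer seed for the synthetic cohort.
#' @param data optional pre-built input list (`movements`, `deaths`,
#'   `age_tables`, optionally `truth`), as returned by [simulate_cohort()].
#' @param threshold linkage acceptance threshold.
#' @param include_uncertain include uncertain matches (sensitivity switch).
#' @param truncation_caps per-location caps in days for
#'   [truncate_overlong()].
#' @param bins standardization bins from [age_bins_4yr()].
#' @param fit_hazards set `FALSE` to skip hazard/survival stages (faster).
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the manifest as JSON.
#' @return list of class `carcmort_run`: `clusters`, `matches`,
#'   `linkage_metrics`, `episodes`, `person_time`, `deaths_classified`,
#'   `rates`, `hazards`, `reduced_cohort`, `km`, `logrank`, `manifest`,
#'   `accounting`.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = config$seed,
                         data = NULL, threshold = 0.90,
                         include_uncertain = FALSE,
                         truncation_caps = c(police = 30, semi_open = 730,
                                             youth = 1095),
                         bins = age_bins_4yr(), fit_hazards = TRUE,
                         causes = c("all", BROAD_CAUSES),
                         out_dir = NULL) {
  if (is.null(data)) data <- simulate_cohort(config, seed)
  movements <- data$movements
  registry <- data$deaths
  window <- config$study_window

  # --- identity resolution ------------------------------------------------
  clusters <- deduplicate_movements(movements)
  members <- cluster_members(clusters)
  last_mv <- movements |>
    inner_join(members, by = "row_id") |>
    group_by(.data$person_uid) |>
    summarise(last_date = max(.data$event_date), .groups = "drop")
  matches <- link_deaths(clusters, registry, threshold = threshold,
                         include_uncertain = include_uncertain,
                         last_movement = last_mv)
  linkage_metrics <- NULL
  if (!is.null(data$truth)) {
    linkage_metrics <- suppressWarnings(
      evaluate_linkage(matches, data$truth$rows, clusters, registry))
  }
  accepted <- filter(matches, .data$accepted)
  # at most one registry row per person: keep the best-scoring match
  accepted <- accepted |>
    arrange(dplyr::desc(.data$combined_score)) |>
    distinct(.data$person_uid, .keep_all = TRUE)

  # --- event harmonization and episodes ----------------------------------
  persons <- transmute(clusters, person_uid = .data$person_uid,
                       sex = .data$sex)
  events <- movements |>
    inner_join(members, by = "row_id") |>
    select("person_uid", "event_type", "facility_type", "event_date")
  linked <- accepted |>
    inner_join(registry, by = c("death_row_id" = "row_id"))
  mv_death <- events |>
    filter(.data$event_type == "death") |>
    group_by(.data$person_uid) |>
    summarise(mv_death_date = min(.data$event_date), .groups = "drop")
  reg_death <- linked |>
    group_by(.data$person_uid) |>
    summarise(reg_death_date = min(.data$death_date), .groups = "drop")
  death_dates <- dplyr::full_join(mv_death, reg_death, by = "person_uid") |>
    mutate(death_date = pmin(.data$mv_death_date, .data$reg_death_date,
                             na.rm = TRUE))
  events <- events |>
    filter(.data$event_type != "death") |>
    left_join(select(death_dates, "person_uid", "death_date"),
              by = "person_uid") |>
    filter(is.na(.data$death_date) | .data$event_date <= .data$death_date) |>
    select(-"death_date") |>
    bind_rows(transmute(death_dates, person_uid = .data$person_uid,
                        event_type = "death",
                        facility_type = NA_character_,
                        event_date = .data$death_date))
  episodes <- build_episodes(events, window) |>
    truncate_overlong(truncation_caps)
  episodes_any_release <- build_episodes(events, window,
                                         release_from = FACILITY_TYPES) |>
    truncate_overlong(truncation_caps)

  # --- death classification ----------------------------------------------
  dloc <- episodes |>
    filter(.data$end_reason == "death") |>
    select("person_uid", "location", episode_start = "start")
  deaths_classified <- linked |>
    left_join(dloc, by = "person_uid") |>
    mutate(population = case_when(
      .data$location %in% FACILITY_TYPES ~ "custody",
      .data$location == "post_release" ~ "post_release",
      TRUE ~ "other"))
  cause_map <- load_cause_map()
  ca <- map_icd10(deaths_classified$icd10_code,
                  in_custody = deaths_classified$population == "custody",
                  sex = deaths_classified$sex, map = cause_map)
  deaths_classified$intermediate_cause <- ca$intermediate_cause
  deaths_classified$broad_cause <- ca$broad_cause
  # unlinked movement-log deaths: all-cause hazard analyses only
  log_unmatched <- anti_join(mv_death, accepted, by = "person_uid")

  # --- person-time ---------------------------------------------------------
  pt_custody <- tabulate_person_time(
    filter(episodes, .data$location %in% FACILITY_TYPES), persons,
    by = c("location", "sex", "calendar_year"))
  pt_post <- tabulate_person_time(
    filter(episodes, .data$location == "post_release"), persons,
    by = c("sex", "release_year", "years_since_release"))
  pt_post_any <- tabulate_person_time(
    filter(episodes_any_release, .data$location == "post_release"), persons,
    by = c("sex", "release_year", "years_since_release"))

  # --- age structure -------------------------------------------------------
  inc_dists <- fine_dists_from_binned(data$age_tables$incarcerated,
                                      bounds = c(18L, 95L))
  pop_dists <- fine_dists_from_binned(data$age_tables$population,
                                      bounds = c(14L, 95L))
  custody_age <- allocate_cells_by_age(
    filter(pt_custody, .data$location != "youth"), inc_dists, bins,
    extra = "location")
  std_weights <- custody_age |>
    group_by(.data$sex, .data$age_bin) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop") |>
    group_by(.data$sex) |>
    mutate(weight = .data$person_years / sum(.data$person_years)) |>
    ungroup() |>
    select("sex", "age_bin", "weight")
  post_deaths_fine <- deaths_classified |>
    filter(.data$population == "post_release", !is.na(.data$age_at_death)) |>
    mutate(release_year = as.integer(format(.data$episode_start, "%Y")),
           ysr = pmax(0L, as.integer(floor(
             interval_years(.data$episode_start, .data$death_date)))),
           age = as.integer(.data$age_at_death))
  post_age <- postrelease_age_py(pt_post, inc_dists, post_deaths_fine,
                                 episodes, bins, persons)
  post_any_age <- postrelease_age_py(pt_post_any, inc_dists,
                                     tibble(), episodes_any_release, bins,
                                     persons)
  pop_age <- allocate_cells_by_age(
    data$age_tables$population |>
      group_by(sex = .data$sex, calendar_year = .data$year) |>
      summarise(person_years = sum(.data$person_years), .groups = "drop"),
    pop_dists, bins, keep_young = TRUE)
  # custody time of minors (youth detention) is subtracted from the young band
  youth_py <- pt_custody |>
    filter(.data$location == "youth") |>
    group_by(.data$sex) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop") |>
    mutate(age_bin = "14-17")
  custody_cells <- custody_age |>
    group_by(.data$sex, .data$age_bin) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop") |>
    bind_rows(youth_py)
  noninc_py <- non_incarcerated_denominator(
    pop_age |>
      group_by(.data$sex, .data$age_bin) |>
      summarise(person_years = sum(.data$person_years), .groups = "drop"),
    custody_cells, post_any_age)

  # --- rate tables ---------------------------------------------------------
  noninc_deaths <- registry |>
    anti_join(accepted, by = c("row_id" = "death_row_id"))
  nic <- map_icd10(noninc_deaths$icd10_code, in_custody = FALSE,
                   sex = noninc_deaths$sex, map = cause_map)
  noninc_deaths$intermediate_cause <- nic$intermediate_cause
  noninc_deaths$broad_cause <- nic$broad_cause
  rates <- rates_table(deaths_classified, noninc_deaths, custody_age,
                       post_age, noninc_py, pt_custody, std_weights, bins,
                       causes = causes)

  # --- hazards and survival ------------------------------------------------
  hazards <- NULL; km <- NULL; logrank <- NULL; reduced <- NULL
  if (fit_hazards) {
    spells <- episodes |>
      filter(.data$location == "post_release") |>
      left_join(select(deaths_classified, "person_uid", "broad_cause"),
                by = "person_uid") |>
      mutate(time = interval_years(.data$start, .data$end),
             death = .data$end_reason == "death",
             cause = if_else(.data$death, .data$broad_cause, NA_character_))
    hazards <- list()
    hazards$all <- try_hazard(spells$time, spells$death, "all")
    hazards$violence_suicide <- try_hazard(
      spells$time, spells$death & spells$cause %in% c("violence", "suicide"),
      "violence+suicide")
    hazards$other <- try_hazard(
      spells$time,
      spells$death & !is.na(spells$cause) &
        !spells$cause %in% c("violence", "suicide"),
      "other causes")
    reduced <- build_reduced_cohort(
      episodes,
      deaths_classified |> select("person_uid", "death_date", "broad_cause"),
      study_window = window)
    if (!is.null(reduced) && nrow(reduced) > 0 && sum(reduced$event) > 0) {
      viol <- reduced$event & reduced$cause %in% c("violence", "suicide")
      km <- list(
        violence = km_estimate(reduced$time, viol),
        other = km_estimate(reduced$time, reduced$event & !viol))
      if (nlevels(droplevels(reduced$incarceration_stratum)) >= 2 &&
          sum(viol) > 0) {
        logrank <- log_rank(reduced$time, viol,
                            reduced$incarceration_stratum)
      }
    }
  }

  # --- manifest and accounting --------------------------------------------
  custody_by_fac <- deaths_classified |>
    filter(.data$population == "custody") |>
    count(.data$location) |>
    (\(d) setNames(d$n, d$location))()
  custody_by_fac <- setNames(
    vapply(FACILITY_TYPES, function(f) sum(custody_by_fac[f], na.rm = TRUE),
           numeric(1)), FACILITY_TYPES)
  pt_components <- pt_custody |>
    group_by(.data$location) |>
    summarise(py = sum(.data$person_years), .groups = "drop") |>
    (\(d) setNames(d$py, d$location))()
  log_death_count <- nrow(mv_death)
  manifest <- list(
    seed = seed, threshold = threshold,
    include_uncertain = include_uncertain,
    truncation_caps = as.list(truncation_caps),
    n_movement_rows = nrow(movements),
    n_clusters = nrow(clusters),
    n_registry_rows = nrow(registry),
    n_candidate_pairs = nrow(matches),
    n_accepted = nrow(accepted),
    n_uncertain = sum(matches$status == "uncertain"),
    deaths_custody_by_facility = as.list(custody_by_fac),
    deaths_custody = sum(custody_by_fac),
    deaths_post_release = sum(deaths_classified$population == "post_release"),
    deaths_other_location = sum(deaths_classified$population == "other"),
    log_death_events = log_death_count,
    log_unmatched_deaths = nrow(log_unmatched),
    excluded_missing_age = sum(is.na(deaths_classified$age_at_death)),
    person_years_custody = as.list(pt_components),
    person_years_post_release = sum(pt_post$person_years))
  accounting <- report_accounting(
    custody_deaths_by_facility = custody_by_fac,
    log_reported = log_death_count,
    registry_total = nrow(registry),
    linked_total = nrow(accepted),
    linked_custody = sum(custody_by_fac),
    linked_post_release = manifest$deaths_post_release,
    log_unmatched = nrow(log_unmatched),
    person_time_components = pt_components)

  run <- structure(list(
    clusters = clusters, matches = matches,
    linkage_metrics = linkage_metrics,
    episodes = episodes, person_time = list(custody = pt_custody,
                                            post_release = pt_post),
    deaths_classified = deaths_classified,
    age_structure = list(incarcerated = inc_dists, weights = std_weights,
                         custody_age = custody_age, post_age = post_age,
                         pop_age = pop_age, noninc_py = noninc_py),
    rates = rates, hazards = hazards, reduced_cohort = reduced,
    km = km, logrank = logrank,
    manifest = manifest, accounting = accounting,
    config = config), class = "carcmort_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

try_hazard <- function(time, event, label) {
  tryCatch(smooth_hazard(time, event, cause_set = label),
           carcmort_hazard_error = function(e) NULL)
}

#' @export
print.carcmort_run <- function(x, ...) {
  m <- x$manifest
  cat("<carcmort pipeline run>\n")
  cat(sprintf("  movement rows %d -> persons %d; registry %d -> linked %d\n",
              m$n_movement_rows, m$n_clusters, m$n_registry_rows,
              m$n_accepted))
  cat(sprintf("  deaths: custody %d, post-release %d, other %d; unmatched log deaths %d\n",
              m$deaths_custody, m$deaths_post_release,
              m$deaths_other_location, m$log_unmatched_deaths))
  invisible(x)
}

# single-year age distributions per sex and calendar year from a wide-binned
# table; sparse sex-years fall back to the sex-pooled table
fine_dists_from_binned <- function(tab, bounds) {
  pooled <- tab |>
    group_by(.data$sex, .data$age_low, .data$age_high) |>
    summarise(proportion = mean(.data$proportion), .groups = "drop") |>
    group_by(.data$sex) |>
    mutate(proportion = .data$proportion / sum(.data$proportion)) |>
    ungroup()
  templates <- pooled |>
    distinct(.data$sex, .data$age_low, .data$age_high)
  fit_adjusted <- function(binned, sx) {
    binned <- templates |>
      filter(.data$sex == sx) |>
      select(-"sex") |>
      left_join(binned |>
                  group_by(.data$age_low, .data$age_high) |>
                  summarise(proportion = sum(.data$proportion),
                            .groups = "drop"),
                by = c("age_low", "age_high")) |>
      mutate(proportion = dplyr::coalesce(.data$proportion, 0)) |>
      arrange(.data$age_low)
    binned$proportion <- binned$proportion / sum(binned$proportion)
    fit <- fit_truncated_negbin(binned, bounds)
    adjust_to_bins(fit$fine, binned)
  }
  pooled_fits <- purrr::map_dfr(unique(pooled$sex), function(sx) {
    mutate(fit_adjusted(filter(pooled, .data$sex == sx), sx), sex = sx)
  })
  combos <- distinct(tab, .data$sex, .data$year)
  purrr::pmap_dfr(combos, function(sex, year) {
    sub <- tab[tab$sex == sex & tab$year == year, ]
    fine <- if (sum(sub$proportion > 0) >= 3) {
      tryCatch(fit_adjusted(sub, sex),
               carcmort_fit_error = function(e)
                 select(filter(pooled_fits, .data$sex == !!sex), -"sex"),
               carcmort_config_error = function(e)
                 select(filter(pooled_fits, .data$sex == !!sex), -"sex"))
    } else {
      select(filter(pooled_fits, .data$sex == !!sex), -"sex")
    }
    mutate(fine, sex = sex, year = year)
  })
}

# multiply person-time cells by the matching (sex, year) fine distribution
# and aggregate to standardization bins; ages below the first bin are kept
# as a "14-17" band when keep_young is set
allocate_cells_by_age <- function(cells, dists, bins, extra = character(),
                                  keep_young = FALSE) {
  joined <- cells |>
    inner_join(dists, by = c("sex", "calendar_year" = "year"),
               relationship = "many-to-many")
  joined$age_bin <- assign_age_bin(joined$age, bins)
  if (keep_young) {
    joined$age_bin[is.na(joined$age_bin)] <- "14-17"
  } else {
    joined <- filter(joined, !is.na(.data$age_bin))
  }
  joined |>
    group_by(across(dplyr::all_of(c("sex", "calendar_year", extra,
                                    "age_bin")))) |>
    summarise(person_years = sum(.data$person_years * .data$proportion),
              .groups = "drop")
}

# age-stratified post-release person-time: release-year cohorts carry the
# incarcerated age structure of their release year, aged one year per year
# since release, depleted by observed age-specific deaths
postrelease_age_py <- function(pt_post, inc_dists, deaths_fine, episodes,
                               bins, persons = NULL) {
  if (nrow(pt_post) == 0) {
    return(tibble(sex = character(), age_bin = character(),
                  person_years = numeric()))
  }
  releases <- episodes |>
    filter(.data$location == "post_release") |>
    mutate(release_year = as.integer(format(.data$start, "%Y")))
  if (!is.null(persons)) {
    releases <- left_join(releases,
                          select(persons, "person_uid", "sex"),
                          by = "person_uid")
  } else {
    releases$sex <- NA_character_
  }
  combos <- distinct(pt_post, .data$sex, .data$release_year)
  out <- purrr::pmap_dfr(combos, function(sex, release_year) {
    d0 <- inc_dists[inc_dists$sex == sex & inc_dists$year == release_year, ]
    if (nrow(d0) == 0) {
      d0 <- inc_dists[inc_dists$sex == sex, ] |>
        group_by(.data$age) |>
        summarise(proportion = mean(.data$proportion), .groups = "drop")
    }
    d0 <- select(d0, "age", "proportion")
    cohort_n <- max(1, sum(releases$release_year == release_year &
                             (is.na(releases$sex) | releases$sex == sex)))
    cells <- pt_post[pt_post$sex == sex &
                       pt_post$release_year == release_year, ]
    dth <- if (nrow(deaths_fine) == 0) deaths_fine else
      deaths_fine[deaths_fine$sex == sex &
                    deaths_fine$release_year == release_year, , drop = FALSE]
    purrr::pmap_dfr(cells, function(years_since_release, person_years, ...) {
      k <- years_since_release
      dk <- age_forward(d0, k)
      wt <- dk$proportion * cohort_n
      if (nrow(dth) > 0) {
        for (j in 0:k) {
          dj <- dth[dth$ysr == j, , drop = FALSE]
          if (nrow(dj) == 0) next
          aged <- pmin(dj$age + (k - j), max(dk$age))
          mult <- if (j == k) 0.5 else 1
          for (a in unique(aged)) {
            hit <- which(dk$age == a)
            wt[hit] <- wt[hit] - mult * sum(aged == a)
          }
        }
        wt <- pmax(0, wt)
      }
      ab <- assign_age_bin(dk$age, bins)
      keep <- !is.na(ab) & wt > 0
      if (!any(keep)) return(NULL)
      tibble(sex = sex, age_bin = ab[keep],
             person_years = person_years * wt[keep] / sum(wt[keep]))
    })
  })
  out |>
    group_by(.data$sex, .data$age_bin) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop")
}

# assemble the standardized rate/IRR table for every population and broad
# cause, per sex
rates_table <- function(deaths_classified, noninc_deaths, custody_age,
                        post_age, noninc_py, pt_custody, std_weights, bins,
                        causes = c("all", BROAD_CAUSES)) {
  adult_deaths <- function(d) {
    filter(d, !is.na(.data$age_at_death), .data$age_at_death >= 18)
  }
  count_by_bin <- function(d) {
    d$age_bin <- assign_age_bin(d$age_at_death, bins)
    d |> filter(!is.na(.data$age_bin)) |>
      count(.data$sex, .data$age_bin, name = "deaths")
  }
  pops <- list(
    closed = list(
      deaths = filter(deaths_classified, .data$population == "custody",
                      .data$location == "closed"),
      py = filter(custody_age, .data$location == "closed")),
    semi_open = list(
      deaths = filter(deaths_classified, .data$population == "custody",
                      .data$location == "semi_open"),
      py = filter(custody_age, .data$location == "semi_open")),
    police = list(
      deaths = filter(deaths_classified, .data$population == "custody",
                      .data$location == "police"),
      py = filter(custody_age, .data$location == "police")),
    post_release = list(
      deaths = filter(deaths_classified, .data$population == "post_release"),
      py = post_age))
  noninc_adult <- adult_deaths(noninc_deaths)
  out <- list()
  for (sx in c("male", "female")) {
    w <- std_weights |> filter(.data$sex == sx) |>
      select("age_bin", "weight")
    if (nrow(w) == 0) next
    ref_py <- noninc_py |> filter(.data$sex == sx, .data$age_bin != "14-17")
    for (cz in causes) {
      pick_cause <- function(d) {
        if (cz == "all") d else filter(d, .data$broad_cause == cz)
      }
      ref_d <- count_by_bin(pick_cause(noninc_adult) |>
                              filter(.data$sex == sx))
      ref_rates <- ref_py |>
        left_join(ref_d, by = c("sex", "age_bin")) |>
        mutate(deaths = dplyr::coalesce(.data$deaths, 0L)) |>
        filter(.data$person_years > 0)
      if (nrow(ref_rates) == 0) next
      asr0 <- standardize(
        age_specific_rate(ref_rates$deaths, ref_rates$person_years,
                          age_bin = ref_rates$age_bin), w)
      out[[length(out) + 1L]] <- tibble(
        population = "non_incarcerated", sex = sx, cause = cz,
        deaths = sum(ref_rates$deaths),
        person_years = sum(ref_rates$person_years),
        rate_per_100k = asr0$rate_per_100k,
        ci_low = asr0$ci_low, ci_high = asr0$ci_high,
        irr = NA_real_, irr_low = NA_real_, irr_high = NA_real_,
        method = "reference")
      for (pn in names(pops)) {
        d <- pick_cause(adult_deaths(pops[[pn]]$deaths)) |>
          filter(.data$sex == sx)
        pyt <- pops[[pn]]$py |> filter(.data$sex == sx)
        if (nrow(pyt) == 0 || sum(pyt$person_years) <= 0) next
        dd <- count_by_bin(d)
        cell <- pyt |>
          group_by(.data$age_bin) |>
          summarise(person_years = sum(.data$person_years),
                    .groups = "drop") |>
          left_join(select(dd, -"sex"), by = "age_bin") |>
          mutate(deaths = dplyr::coalesce(.data$deaths, 0L)) |>
          filter(.data$person_years > 0)
        asr1 <- standardize(
          age_specific_rate(cell$deaths, cell$person_years,
                            age_bin = cell$age_bin), w)
        ir <- tryCatch(irr_standardized(asr1, asr0),
                       carcmort_rate_error = function(e)
                         tibble(irr = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_, method = "f_approx"))
        out[[length(out) + 1L]] <- tibble(
          population = pn, sex = sx, cause = cz,
          deaths = sum(cell$deaths),
          person_years = sum(cell$person_years),
          rate_per_100k = asr1$rate_per_100k,
          ci_low = asr1$ci_low, ci_high = asr1$ci_high,
          irr = ir$irr, irr_low = ir$ci_low, irr_high = ir$ci_high,
          method = ir$method)
      }
      # youth detention: crude rates against the non-incarcerated young band
      yd <- pick_cause(deaths_classified) |>
        filter(.data$population == "custody", .data$location == "youth",
               .data$sex == sx)
      ypy <- pt_custody |>
        filter(.data$location == "youth", .data$sex == sx) |>
        summarise(py = sum(.data$person_years)) |> pull(.data$py)
      ref_young_py <- noninc_py |>
        filter(.data$sex == sx, .data$age_bin == "14-17") |>
        pull(.data$person_years)
      ref_young_d <- pick_cause(noninc_deaths) |>
        filter(.data$sex == sx, !is.na(.data$age_at_death),
               .data$age_at_death < 18) |> nrow()
      if (length(ypy) == 1 && ypy > 0 && length(ref_young_py) == 1 &&
          ref_young_py > 0) {
        cr <- age_specific_rate(nrow(yd), ypy, age_bin = "youth_crude")
        ir <- if (nrow(yd) + ref_young_d > 0) {
          irr_exact(nrow(yd), ypy, ref_young_d, ref_young_py)
        } else {
          tibble(irr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 method = "poisson_exact")
        }
        out[[length(out) + 1L]] <- tibble(
          population = "youth", sex = sx, cause = cz,
          deaths = nrow(yd), person_years = ypy,
          rate_per_100k = cr$rate_per_100k, ci_low = cr$ci_low,
          ci_high = cr$ci_high,
          irr = ir$irr, irr_low = ir$ci_low, irr_high = ir$ci_high,
          method = ir$method)
      }
    }
  }
  bind_rows(out)
}

#' Headline accounting ratios and shares
#'
#' Reproduces the accounting identities of a linkage run from its counts:
#' under-reporting ratios of identified custody deaths against externally
#' reported counts, facility shares of custody deaths, linked fractions of
#' the mortality registry, the share of movement-log deaths with no registry
#' match, and the person-time decomposition. Any ratio with a zero
#' denominator is returned as `NA` with a flag.
#'
#' @param custody_deaths_by_facility named vector of custody death counts by
#'   facility type.
#' @param national_reported externally reported custody death count (national
#'   prison administration), if any.
#' @param log_reported custody death count documented in the movement log.
#' @param registry_total total mortality-registry rows.
#' @param linked_total,linked_custody,linked_post_release linked death
#'   counts.
#' @param log_unmatched movement-log deaths with no registry match.
#' @param person_time_components named vector of person-years by facility.
#' @return tibble `quantity`, `value`, `flag` (percent scale where the
#'   quantity name ends in `_pct`).
#' @export
report_accounting <- function(custody_deaths_by_facility = NULL,
                              national_reported = NULL, log_reported = NULL,
                              registry_total = NULL, linked_total = NULL,
                              linked_custody = NULL,
                              linked_post_release = NULL,
                              log_unmatched = NULL,
                              person_time_components = NULL) {
  rows <- list()
  add <- function(quantity, num, den = 1, pct = FALSE) {
    flag <- ""
    val <- if (is.null(num) || is.null(den)) {
      return(invisible(NULL))
    } else if (length(den) == 1 && den == 0) {
      flag <- "zero_denominator"; NA_real_
    } else {
      num / den * (if (pct) 100 else 1)
    }
    rows[[length(rows) + 1L]] <<- tibble(quantity = quantity, value = val,
                                         flag = flag)
  }
  custody_total <- if (!is.null(custody_deaths_by_facility)) {
    sum(custody_deaths_by_facility)
  } else NULL
  if (!is.null(custody_total)) {
    add("custody_deaths_total", custody_total)
    for (f in names(custody_deaths_by_facility)) {
      add(paste0("custody_share_", f, "_pct"),
          custody_deaths_by_facility[[f]], custody_total, pct = TRUE)
    }
  }
  if (!is.null(national_reported)) {
    add("underreporting_ratio_vs_national", custody_total, national_reported)
  }
  if (!is.null(log_reported)) {
    add("underreporting_ratio_vs_log", custody_total, log_reported)
  }
  if (!is.null(registry_total)) {
    add("linked_fraction_total_pct", linked_total, registry_total, pct = TRUE)
    add("linked_fraction_custody_pct", linked_custody, registry_total,
        pct = TRUE)
    add("linked_fraction_post_release_pct", linked_post_release,
        registry_total, pct = TRUE)
  }
  if (!is.null(log_unmatched) && !is.null(log_reported)) {
    add("log_deaths_unmatched_pct", log_unmatched, log_reported,
        pct = TRUE)
  }
  if (!is.null(person_time_components)) {
    add("person_years_incarceration_total", sum(person_time_components))
    for (f in names(person_time_components)) {
      add(paste0("person_years_", f), person_time_components[[f]])
    }
  }
  bind_rows(rows)
}

# write run outputs as plain-text tables plus a JSON manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$clusters |> select(-"member_row_ids"),
                   file.path(out_dir, "clusters.csv"))
  readr::write_csv(run$matches, file.path(out_dir, "matches.csv"))
  readr::write_csv(run$episodes, file.path(out_dir, "episodes.csv"))
  readr::write_csv(run$person_time$custody,
                   file.path(out_dir, "person_time_custody.csv"))
  readr::write_csv(run$person_time$post_release,
                   file.path(out_dir, "person_time_post_release.csv"))
  readr::write_csv(run$deaths_classified |>
                     select(-dplyr::any_of(".person_uid")),
                   file.path(out_dir, "deaths_classified.csv"))
  readr::write_csv(run$rates, file.path(out_dir, "rates.csv"))
  readr::write_csv(run$accounting, file.path(out_dir, "accounting.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
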