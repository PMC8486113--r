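#' Default wide-binned age structure of the incarcerated population
#'
#' Proportion of the adult incarcerated population in each wide age bin,
#' in the format national prison administrations publish (one row per bin,
#' inclusive bounds). The default emulates a young, male-dominated prison
#' population: most mass between 18 and 35, a thin tail above 60.
#'
#' @param sex `"male"` or `"female"`; the default tables differ slightly.
#' @return tibble with columns `age_low`, `age_high`, `proportion`.
#' @export
default_age_bins <- function(sex = "male") {
  if (identical(sex, "female")) {
    tibble(
      age_low  = c(18L, 25L, 30L, 35L, 46L, 61L),
      age_high = c(24L, 29L, 34L, 45L, 60L, 80L),
      proportion = c(0.265, 0.206, 0.190, 0.230, 0.098, 0.011)
    )
  } else {
    tibble(
      age_low  = c(18L, 25L, 30L, 35L, 46L, 61L),
      age_high = c(24L, 29L, 34L, 45L, 60L, 80L),
      proportion = c(0.233, 0.244, 0.198, 0.223, 0.089, 0.013)
    )
  }
}

#' Default age- and sex-specific baseline mortality
#'
#' All-cause mortality of the non-incarcerated reference population, per
#' 100,000 person-years, piecewise constant over age bands. The male schedule
#' is roughly that of an upper-middle-income country with a high burden of
#' interpersonal violence among young men.
#'
#' @param flat optional single rate per 100,000; when supplied, the schedule
#'   is constant over age (useful for analytically checkable simulations).
#' @return tibble with columns `sex`, `age_low`, `age_high`, `rate_100k`.
#' @export
default_baseline_mortality <- function(flat = NULL) {
  lows  <- c(14, 18, 25, 30, 35, 40, 45, 50, 55, 60, 65)
  highs <- c(17, 24, 29, 34, 39, 44, 49, 54, 59, 64, 95)
  male   <- c(80, 150, 170, 190, 220, 280, 360, 520, 750, 1100, 2600)
  female <- c(40,  60,  70,  85, 110, 150, 220, 330, 480,  700, 2000)
  if (!is.null(flat)) {
    male <- rep(flat, length(lows))
    female <- rep(flat, length(lows))
  }
  bind_rows(
    tibble(sex = "male", age_low = lows, age_high = highs, rate_100k = male),
    tibble(sex = "female", age_low = lows, age_high = highs, rate_100k = female)
  )
}

#' Default cause-of-death mix by state
#'
#' Distribution of deaths over broad cause categories, conditional on death,
#' for each occupancy state. Custody states are violence/suicide heavy;
#' the never-incarcerated reference is dominated by noncommunicable disease.
#' Together with the all-cause state rate ratios this fixes the implied
#' cause-specific rate ratios (rr_cause = rr_all * mix_state / mix_reference).
#'
#' @return tibble with columns `state`, one column per broad cause; rows sum to 1.
#' @export
default_cause_mix <- function() {
  m <- rbind(
    free_never   = c(0.12, 0.02, 0.10, 0.55, 0.12, 0.09),
    closed       = c(0.32, 0.08, 0.22, 0.26, 0.01, 0.11),
    semi_open    = c(0.45, 0.04, 0.14, 0.25, 0.03, 0.09),
    police       = c(0.40, 0.17, 0.08, 0.22, 0.02, 0.11),
    youth        = c(0.65, 0.08, 0.04, 0.12, 0.04, 0.07),
    post_release = c(0.30, 0.03, 0.12, 0.38, 0.09, 0.08),
    free_other   = c(0.22, 0.03, 0.11, 0.45, 0.11, 0.08)
  )
  colnames(m) <- BROAD_CAUSES
  out <- as_tibble(m)
  out$state <- rownames(m)
  select(out, "state", dplyr::all_of(BROAD_CAUSES))
}

#' Default all-cause mortality rate ratios by state
#'
#' Multipliers applied to the age- and sex-specific baseline hazard while an
#' individual occupies each state. Defaults are round values of the size
#' reported for carceral systems in middle-income settings.
#'
#' @return named numeric vector over states.
#' @export
default_state_rate_ratios <- function() {
  c(free_never = 1.0, closed = 1.3, semi_open = 2.4, police = 3.1,
    youth = 8.1, post_release = 3.0, free_other = 1.5)
}

#' Default career transition intensities
#'
#' Continuous-time Markov intensities (events per person-year) for movement
#' through the carceral system. `entry_mix` splits adult admissions across
#' facility types; arrests of minors go to youth detention.
#'
#' @return named list of rates and mixes.
#' @export
default_career_rates <- function() {
  list(
    arrest = 0.020,            # adult arrests per free person-year
    minor_arrest = 0.050,      # arrests of minors (to youth detention)
    entry_mix = c(closed = 0.35, semi_open = 0.05, police = 0.60),
    transfer = c(police_to_closed = 6.0, closed_to_semi_open = 0.30,
                 semi_open_to_closed = 0.50),
    release = c(closed = 0.80, semi_open = 2.0, police = 12.0, youth = 1.5),
    reincarceration = c(post_release = 0.15, free_other = 0.10)
  )
}

#' Name corruption model
#'
#' @param char_sub per-character substitution probability.
#' @param token_drop probability that one middle token is dropped.
#' @param token_swap probability that two adjacent tokens are swapped.
#' @param missing_mother probability the mother's name field is blank.
#' @return list of class `carcmort_name_noise`.
#' @export
name_noise <- function(char_sub = 0.02, token_drop = 0.01, token_swap = 0.01,
                       missing_mother = 0.10) {
  out <- list(char_sub = char_sub, token_drop = token_drop,
              token_swap = token_swap, missing_mother = missing_mother)
  for (f in names(out)) check_prob(out[[f]], paste0("name_noise$", f))
  structure(out, class = "carcmort_name_noise")
}

#' Configuration for the synthetic registry generator
#'
#' Bundles every knob of the generative model: cohort size and sex ratio, the
#' study window, the target age structure, career transition intensities,
#' the baseline mortality schedule, state rate ratios (with an optional
#' post-release decay profile by year since release), the cause mix, the name
#' noise model, and registry imperfection probabilities.
#'
#' @param n_individuals number of simulated residents (incarcerated or not).
#' @param study_window length-2 Date vector, inclusive start / exclusive end.
#' @param sex_ratio proportion male.
#' @param age_binned_target list with elements `male`, `female`: wide-binned
#'   adult age tables as from [default_age_bins()].
#' @param minor_fraction fraction of the cohort aged 14-17 at window start.
#' @param career_rates list as from [default_career_rates()].
#' @param baseline_mortality tibble as from [default_baseline_mortality()].
#' @param cause_mix tibble as from [default_cause_mix()].
#' @param state_rate_ratios named vector as from [default_state_rate_ratios()].
#' @param postrelease_decay numeric multipliers on the post-release rate ratio
#'   by integer year since release (recycled to the last value); default flat.
#' @param name_noise list as from [name_noise()].
#' @param duplicate_id_prob probability an individual carries a second
#'   internal ID in the movement log.
#' @param custody_death_logged_prob probability a custody death generates a
#'   death event row in the movement log.
#' @param registry_missing_prob probability a death is absent from the
#'   mortality registry (underreporting).
#' @param age_missing_prob probability the registry age-at-death is blank.
#' @param y20_misreport_prob probability a custody death of a man from
#'   violence or suicide is certified as "hanging, strangulation and
#'   suffocation, undetermined intent" (Y20), emulating the reporting quirk
#'   the in-custody reclassification rule exists for.
#' @param adult_age age threshold separating youth detention from adult
#'   facilities.
#' @param seed integer seed recorded in the config (used by
#'   [simulate_cohort()] when no explicit seed is given).
#' @return validated list of class `carcmort_config`.
#' @export
synthetic_config <- function(n_individuals = 20000,
                             study_window = as.Date(c("2009-01-01", "2019-01-01")),
                             sex_ratio = 0.92,
                             age_binned_target = list(male = default_age_bins("male"),
                                                      female = default_age_bins("female")),
                             minor_fraction = 0.05,
                             career_rates = default_career_rates(),
                             baseline_mortality = default_baseline_mortality(),
                             cause_mix = default_cause_mix(),
                             state_rate_ratios = default_state_rate_ratios(),
                             postrelease_decay = 1.0,
                             name_noise = carcmort::name_noise(),
                             duplicate_id_prob = 0.02,
                             custody_death_logged_prob = 0.90,
                             registry_missing_prob = 0.02,
                             age_missing_prob = 0.01,
                             y20_misreport_prob = 0.04,
                             adult_age = 18,
                             seed = 1L) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1 ||
      n_individuals < 0 || n_individuals != floor(n_individuals)) {
    stop_config("n_individuals", "must be a single non-negative integer")
  }
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || any(is.na(study_window)) ||
      study_window[2] <= study_window[1]) {
    stop_config("study_window", "must be two dates with end after start")
  }
  check_prob(sex_ratio, "sex_ratio")
  check_prob(minor_fraction, "minor_fraction")
  check_prob(duplicate_id_prob, "duplicate_id_prob")
  check_prob(custody_death_logged_prob, "custody_death_logged_prob")
  check_prob(registry_missing_prob, "registry_missing_prob")
  check_prob(age_missing_prob, "age_missing_prob")
  check_prob(y20_misreport_prob, "y20_misreport_prob")
  for (s in c("male", "female")) {
    tab <- age_binned_target[[s]]
    if (is.null(tab)) stop_config("age_binned_target", paste("missing table for", s))
    validate_binned_age_table(tab, field = paste0("age_binned_target$", s))
  }
  check_rate(unlist(career_rates[c("arrest", "minor_arrest")]), "career_rates")
  check_rate(career_rates$transfer, "career_rates$transfer")
  check_rate(career_rates$release, "career_rates$release")
  check_rate(career_rates$reincarceration, "career_rates$reincarceration")
  mix <- career_rates$entry_mix
  if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    stop_config("career_rates$entry_mix", "must be nonnegative and sum to 1")
  }
  check_rate(baseline_mortality$rate_100k, "baseline_mortality")
  if (!all(STATES %in% cause_mix$state)) {
    stop_config("cause_mix", "must contain a row for every state")
  }
  mix_sums <- rowSums(as.matrix(cause_mix[, BROAD_CAUSES]))
  if (any(abs(mix_sums - 1) > 1e-9)) {
    stop_config("cause_mix", "each state's cause mix must sum to 1 (tol 1e-9)")
  }
  if (!all(STATES %in% names(state_rate_ratios))) {
    stop_config("state_rate_ratios", "must name every state")
  }
  check_rate(state_rate_ratios, "state_rate_ratios")
  check_rate(postrelease_decay, "postrelease_decay")
  if (!inherits(name_noise, "carcmort_name_noise")) {
    name_noise <- do.call(carcmort::name_noise, as.list(name_noise))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    study_window = study_window,
    sex_ratio = sex_ratio,
    age_binned_target = age_binned_target,
    minor_fraction = minor_fraction,
    career_rates = career_rates,
    baseline_mortality = baseline_mortality,
    cause_mix = cause_mix,
    state_rate_ratios = state_rate_ratios,
    postrelease_decay = postrelease_decay,
    name_noise = name_noise,
    duplicate_id_prob = duplicate_id_prob,
    custody_death_logged_prob = custody_death_logged_prob,
    registry_missing_prob = registry_missing_prob,
    age_missing_prob = age_missing_prob,
    y20_misreport_prob = y20_misreport_prob,
    adult_age = adult_age,
    seed = as.integer(seed)
  ), class = "carcmort_config")
}

validate_binned_age_table <- function(tab, field = "binned age table",
                                      tol = 1e-6) {
  need <- c("age_low", "age_high", "proportion")
  if (!all(need %in% names(tab))) {
    stop_config(field, "needs columns age_low, age_high, proportion")
  }
  tab <- arrange(tab, .data$age_low)
  if (any(tab$proportion < 0)) stop_config(field, "negative proportion")
  if (abs(sum(tab$proportion) - 1) > tol) {
    stop_config(field, "proportions must sum to 1")
  }
  if (any(tab$age_high < tab$age_low)) stop_config(field, "bin bounds inverted")
  if (nrow(tab) > 1 && any(tab$age_low[-1] != tab$age_high[-nrow(tab)] + 1L)) {
    stop_config(field, "bins must be contiguous and non-overlapping")
  }
  invisible(tab)
}

#' @export
print.carcmort_config <- function(x, ...) {
  cat("<carcmort synthetic registry config>\n")
  cat(sprintf("  individuals: %d (%.0f%% male, %.0f%% minors)\n",
              x$n_individuals, 100 * x$sex_ratio, 100 * x$minor_fraction))
  cat(sprintf("  window: %s .. %s\n", x$study_window[1], x$study_window[2]))
  rr <- x$state_rate_ratios
  cat("  state rate ratios:",
      paste(sprintf("%s=%.2g", names(rr), rr), collapse = ", "), "\n")
  invisible(x)
}
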