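#' Write a synthetic-registry configuration to YAML
#'
#' @param config a [synthetic_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$study_window <- as.character(x$study_window)
  x$name_noise <- unclass(x$name_noise)
  for (f in c("baseline_mortality", "cause_mix")) {
    x[[f]] <- as.list(as.data.frame(x[[f]]))
  }
  x$age_binned_target <- lapply(x$age_binned_target,
                                function(t) as.list(as.data.frame(t)))
  x$state_rate_ratios <- as.list(x$state_rate_ratios)
  x$career_rates <- lapply(x$career_rates, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a synthetic-registry configuration from YAML
#'
#' @param path YAML file written by [write_config_yaml()].
#' @return validated [synthetic_config()].
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  as_tab <- function(l) as_tibble(as.data.frame(l))
  unlist_named <- function(l) unlist(l)
  synthetic_config(
    n_individuals = x$n_individuals,
    study_window = as.Date(unlist(x$study_window)),
    sex_ratio = x$sex_ratio,
    age_binned_target = lapply(x$age_binned_target, as_tab),
    minor_fraction = x$minor_fraction,
    career_rates = list(
      arrest = x$career_rates$arrest,
      minor_arrest = x$career_rates$minor_arrest,
      entry_mix = unlist_named(x$career_rates$entry_mix),
      transfer = unlist_named(x$career_rates$transfer),
      release = unlist_named(x$career_rates$release),
      reincarceration = unlist_named(x$career_rates$reincarceration)),
    baseline_mortality = as_tab(x$baseline_mortality),
    cause_mix = as_tab(x$cause_mix),
    state_rate_ratios = unlist_named(x$state_rate_ratios),
    postrelease_decay = unlist(x$postrelease_decay),
    name_noise = do.call(name_noise, x$name_noise),
    duplicate_id_prob = x$duplicate_id_prob,
    custody_death_logged_prob = x$custody_death_logged_prob,
    registry_missing_prob = x$registry_missing_prob,
    age_missing_prob = x$age_missing_prob,
    y20_misreport_prob = x$y20_misreport_prob,
    adult_age = x$adult_age,
    seed = x$seed)
}
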