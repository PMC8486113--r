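# Shared fixtures, built once per test session. All synthetic, seed-fixed.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# modest noisy cohort for dedup/linkage/episode tests
noisy_cohort <- function() {
  fixture("noisy", function() {
    simulate_cohort(synthetic_config(n_individuals = 3000, seed = 42))
  })
}

# zero-noise cohort: names exact, linkage should be perfect
clean_cohort <- function() {
  fixture("clean", function() {
    simulate_cohort(synthetic_config(
      n_individuals = 3000, seed = 43,
      name_noise = name_noise(0, 0, 0, 0)))
  })
}

# truth-derived events in the shape build_episodes() expects, using the
# true person identifiers (bypasses linkage)
truth_events <- function(cohort) {
  cohort$movements |>
    dplyr::inner_join(cohort$truth$rows, by = "row_id") |>
    dplyr::select(person_uid, event_type, facility_type, event_date)
}

expect_tibble_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
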