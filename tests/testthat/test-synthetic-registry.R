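test_that("an empty cohort yields empty registries and truth", {
  out <- simulate_cohort(synthetic_config(n_individuals = 0, seed = 1))
  expect_equal(nrow(out$movements), 0)
  expect_equal(nrow(out$deaths), 0)
  expect_equal(nrow(out$truth$persons), 0)
})

test_that("zero mortality rates produce no deaths and everyone stays alive", {
  cfg <- synthetic_config(n_individuals = 500, seed = 2,
                          baseline_mortality = default_baseline_mortality(flat = 0))
  out <- simulate_cohort(cfg)
  expect_equal(nrow(out$deaths), 0)
  expect_true(all(out$truth$persons$true_status_at_death == "alive"))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- synthetic_config(n_individuals = 400, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$movements, b$movements)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$truth$persons, b$truth$persons)
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(synthetic_config(sex_ratio = 1.4), "sex_ratio")
  expect_error(synthetic_config(n_individuals = -1), "n_individuals")
  expect_error(synthetic_config(study_window = as.Date(c("2010-01-01", "2009-01-01"))),
               "study_window")
  bad_mix <- default_cause_mix()
  bad_mix$violence[1] <- bad_mix$violence[1] + 0.1
  expect_error(synthetic_config(cause_mix = bad_mix), "cause_mix")
})

test_that("careers with zero transition rates never enter custody", {
  cr <- default_career_rates()
  cr$arrest <- 0; cr$minor_arrest <- 0
  ev <- simulate_career(age = rep(30, 50), career_rates = cr, seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("an absorbing custody state is censored at the window end", {
  cr <- default_career_rates()
  cr$arrest <- 1e4
  cr$entry_mix <- c(closed = 1, semi_open = 0, police = 0)
  cr$release <- c(closed = 0, semi_open = 0, police = 0, youth = 0)
  cr$transfer <- c(police_to_closed = 0, closed_to_semi_open = 0,
                   semi_open_to_closed = 0)
  ev <- simulate_career(age = 30, career_rates = cr, window_years = 10,
                        seed = 2)
  expect_equal(ev$kind, "arrest")
  expect_equal(ev$facility, "closed")
})

test_that("event counts match the Poisson-process expectation", {
  # every state has total exit intensity 2/year, so the number of
  # transitions over 10 years is Poisson(20)
  cr <- list(arrest = 2, minor_arrest = 2,
             entry_mix = c(closed = 0, semi_open = 0, police = 1),
             transfer = c(police_to_closed = 0, closed_to_semi_open = 0,
                          semi_open_to_closed = 0),
             release = c(closed = 0, semi_open = 0, police = 2, youth = 0),
             reincarceration = c(post_release = 2, free_other = 2))
  n <- 4000
  ev <- simulate_career(age = rep(30, n), career_rates = cr,
                        window_years = 10, seed = 3)
  mean_events <- nrow(ev) / n
  se <- sqrt(20 / n)
  expect_lt(abs(mean_events - 20), 3 * se)
})

test_that("youth detention only holds minors", {
  coh <- noisy_cohort()
  ages <- setNames(coh$truth$persons$age_start, coh$truth$persons$person_uid)
  ep <- dplyr::filter(coh$truth$episodes, state == "youth")
  age_at_entry <- ages[ep$person_uid] + ep$start
  expect_true(all(age_at_entry < 18 + 1e-9))
})

test_that("death events are terminal and time-ordered", {
  coh <- noisy_cohort()
  ev <- truth_events(coh)
  ord <- ev |>
    dplyr::group_by(person_uid) |>
    dplyr::arrange(event_date, .by_group = TRUE) |>
    dplyr::summarise(
      sorted = !is.unsorted(event_date),
      death_last = !any(event_type == "death") ||
        which.max(event_type == "death") == dplyr::n() ||
        all(event_date[which(event_type == "death"):dplyr::n()] ==
              event_date[which(event_type == "death")]))
  expect_true(all(ord$sorted))
  expect_true(all(ord$death_last))
})

test_that("perturb_string with zero noise is the identity", {
  nm <- c("MARIA DA SILVA", "JOSE SANTOS")
  expect_identical(perturb_string(nm, name_noise(0, 0, 0, 0)), nm)
})

test_that("forced substitution changes every character", {
  set.seed(1)
  out <- perturb_string("ABCDEFGHIJ", name_noise(1, 0, 0, 0))
  a <- strsplit("ABCDEFGHIJ", "")[[1]]
  b <- strsplit(out, "")[[1]]
  expect_true(all(a != b))
})

test_that("per-character corruption matches the binomial expectation", {
  set.seed(11)
  n <- 10000
  name <- strrep("A", 20)
  out <- perturb_string(rep(name, n), name_noise(0.05, 0, 0, 0))
  d <- as.numeric(utils::adist(name, out))
  se <- sqrt(20 * 0.05 * 0.95 / n)
  expect_lt(abs(mean(d) - 1.0), 3 * se)
})

test_that("truth person-time is conserved: window length minus post-death time", {
  coh <- noisy_cohort()
  wy <- as.numeric(diff(coh$config$study_window)) / 365.25
  tot <- coh$truth$episodes |>
    dplyr::group_by(person_uid) |>
    dplyr::summarise(py = sum(end - start))
  p <- coh$truth$persons
  expected <- ifelse(p$died, p$death_time, wy)
  got <- tot$py[match(p$person_uid, tot$person_uid)]
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("realized adult age-at-entry matches the binned target within 3 SE", {
  coh <- noisy_cohort()
  p <- dplyr::filter(coh$truth$persons, age_start >= 18, sex == "male")
  tab <- dplyr::arrange(coh$config$age_binned_target$male, age_low)
  bin <- findInterval(pmin(p$age_start, max(tab$age_high)), tab$age_low)
  n <- nrow(p)
  counts <- tabulate(bin, nbins = nrow(tab))
  expected <- n * tab$proportion
  se <- sqrt(n * tab$proportion * (1 - tab$proportion))
  expect_true(all(abs(counts - expected) <= 3 * se + 1e-9))
})

test_that("configured post-release rate ratio is realized in the truth table", {
  cfg <- synthetic_config(
    n_individuals = 20000, seed = 5,
    baseline_mortality = default_baseline_mortality(flat = 500))
  coh <- simulate_cohort(cfg)
  ep <- coh$truth$episodes |>
    dplyr::left_join(dplyr::select(coh$truth$persons, person_uid,
                                   true_status_at_death, died),
                     by = "person_uid")
  py <- tapply(ep$end - ep$start, ep$state, sum)
  d <- table(coh$truth$persons$true_status_at_death)
  r1 <- d[["post_release"]] / py[["post_release"]]
  r0 <- d[["free_never"]] / py[["free_never"]]
  ratio <- r1 / r0
  se_log <- sqrt(1 / d[["post_release"]] + 1 / d[["free_never"]])
  expect_lt(abs(log(ratio) - log(3.0)), 3 * se_log)
})
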