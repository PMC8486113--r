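mk_clusters <- function(names, mothers = NULL, ids = NULL) {
  n <- length(names)
  tibble::tibble(
    person_uid = ids %||% sprintf("C%03d", seq_len(n)),
    canonical_name = names,
    canonical_mother_name = mothers %||% rep(NA_character_, n),
    sex = "male", n_rows = 1L,
    member_row_ids = as.list(sprintf("M%03d", seq_len(n))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_registry <- function(names, mothers = NULL) {
  n <- length(names)
  tibble::tibble(row_id = sprintf("D%03d", seq_len(n)), name = names,
                 mother_name = mothers %||% rep(NA_character_, n),
                 sex = "male", death_date = as.Date("2015-01-01"),
                 age_at_death = 40, icd10_code = "I21")
}

test_that("an exact name and mother match is accepted with score 1", {
  cl <- mk_clusters("JOSE SILVA", "MARIA SILVA")
  reg <- mk_registry("JOSE SILVA", "MARIA SILVA")
  m <- link_deaths(cl, reg, threshold = 0.9)
  acc <- dplyr::filter(m, accepted)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$combined_score, 1.0)
})

test_that("a death with no candidate above threshold is not matched", {
  cl <- mk_clusters("JOSE SILVA", "MARIA SILVA")
  reg <- mk_registry("CARLOS PEREIRA", "ANA COSTA")
  m <- link_deaths(cl, reg, threshold = 0.9)
  expect_equal(sum(m$accepted), 0)
})

test_that("an empty registry yields an empty match set", {
  cl <- mk_clusters("JOSE SILVA")
  expect_equal(nrow(link_deaths(cl, mk_registry(character(0)))), 0)
})

test_that("missing mother with multiple perfect name matches is uncertain", {
  cl <- mk_clusters(c("JOSE SILVA", "JOSE SILVA"),
                    c("MARIA SILVA", "ANA COSTA"))
  reg <- mk_registry("JOSE SILVA")  # no mother's name on the death row
  m <- link_deaths(cl, reg, threshold = 0.9)
  expect_equal(sum(m$status == "uncertain"), 1)
  expect_equal(sum(m$accepted), 0)
  m2 <- link_deaths(cl, reg, threshold = 0.9, include_uncertain = TRUE)
  expect_equal(sum(m2$accepted), 1)
})

test_that("evaluate_linkage reproduces confusion-matrix arithmetic", {
  # 10 true person-death pairs; 8 accepted, 2 rejected, plus 1 accepted and
  # 89 rejected false pairs -> sens 0.8, spec 89/90, ppv 8/9
  n <- 10
  clusters <- mk_clusters(sprintf("NAME %02d", 1:n))
  truth_rows <- dplyr::bind_rows(
    tibble::tibble(row_id = sprintf("M%03d", 1:n), table = "movement",
                   person_uid = sprintf("P%02d", 1:n)),
    tibble::tibble(row_id = sprintf("D%03d", 1:n), table = "death",
                   person_uid = sprintf("P%02d", 1:n)))
  true_pairs <- tibble::tibble(
    death_row_id = sprintf("D%03d", 1:n),
    person_uid = sprintf("C%03d", 1:n),
    name_score = 1, mother_score = NA_real_, combined_score = 1,
    status = c(rep("accepted", 8), rep("rejected", 2)))
  grid <- expand.grid(i = 1:n, j = 1:n)
  grid <- grid[grid$i != grid$j, ][1:90, ]
  false_pairs <- tibble::tibble(
    death_row_id = sprintf("D%03d", grid$i),
    person_uid = sprintf("C%03d", grid$j),
    name_score = 0.5, mother_score = NA_real_, combined_score = 0.5,
    status = c("accepted", rep("rejected", 89)))
  cand <- dplyr::bind_rows(true_pairs, false_pairs)
  cand$accepted <- cand$status == "accepted"
  registry <- mk_registry(sprintf("NAME %02d", 1:n))
  met <- evaluate_linkage(cand, truth_rows, clusters, registry)
  expect_equal(met$sensitivity, 0.8)
  expect_equal(met$specificity, 89 / 90)
  expect_equal(met$ppv, 8 / 9)
})

test_that("degenerate linkage metrics are signalled, not fabricated", {
  clusters <- mk_clusters("JOSE SILVA")
  truth_rows <- tibble::tibble(
    row_id = c("M001", "D001"), table = c("movement", "death"),
    person_uid = c("P01", "P01"))
  cand <- tibble::tibble(death_row_id = "D001", person_uid = "C001",
                         name_score = 1, mother_score = NA_real_,
                         combined_score = 1, status = "rejected",
                         accepted = FALSE)
  expect_warning(
    met <- evaluate_linkage(cand, truth_rows, clusters,
                            mk_registry("JOSE SILVA")),
    "ppv")
  expect_equal(met$sensitivity, 0)
  expect_true(is.na(met$ppv))
})

test_that("blocking loses nothing relative to brute force on a small cohort", {
  coh <- noisy_cohort()
  reg <- coh$deaths[1:60, ]
  cl <- deduplicate_movements(coh$movements)
  blocked <- link_deaths(cl, reg, threshold = 0.9)
  # brute force oracle: score every (death, cluster) pair with the same
  # combined-score rule and keep the best at or above threshold
  brute_best <- vapply(seq_len(nrow(reg)), function(i) {
    ns <- name_similarity(reg$name[i], cl$canonical_name)
    ms <- ifelse(is.na(reg$mother_name[i]) |
                   is.na(cl$canonical_mother_name), NA,
                 name_similarity(reg$mother_name[i],
                                 cl$canonical_mother_name))
    comb <- ifelse(is.na(ms), ns, (ns + ms) / 2)
    max(comb)
  }, numeric(1))
  blocked_best <- vapply(seq_len(nrow(reg)), function(i) {
    rows <- blocked[blocked$death_row_id == reg$row_id[i], ]
    if (nrow(rows) == 0) 0 else max(rows$combined_score)
  }, numeric(1))
  hit <- brute_best >= 0.9
  expect_equal(blocked_best[hit], brute_best[hit])
})

test_that("raising the threshold never grows the accepted set", {
  coh <- noisy_cohort()
  cl <- deduplicate_movements(coh$movements)
  reg <- coh$deaths
  prev <- NULL
  for (th in c(0.75, 0.85, 0.92, 0.97)) {
    acc <- link_deaths(cl, reg, threshold = th) |>
      dplyr::filter(accepted)
    key <- paste(acc$death_row_id, acc$person_uid)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("sensitivity falls and specificity rises along a threshold sweep", {
  coh <- noisy_cohort()
  cl <- deduplicate_movements(coh$movements)
  sens <- c(); spec <- c()
  for (th in c(0.75, 0.85, 0.95)) {
    m <- link_deaths(cl, coh$deaths, threshold = th)
    met <- suppressWarnings(
      evaluate_linkage(m, coh$truth$rows, cl, coh$deaths))
    sens <- c(sens, met$sensitivity); spec <- c(spec, met$specificity)
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("select_threshold finds gaps, flags degeneracy, matches a sweep", {
  # perfectly separated -> midpoint of the gap
  out <- select_threshold(c(0.2, 0.3, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$threshold, 0.55)
  # identical scores -> that score, flagged degenerate
  deg <- select_threshold(rep(0.7, 5), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_true(deg$degenerate)
  expect_equal(deg$threshold, 0.7)
  # overlapping beta-distributed scores -> agrees with a brute-force sweep
  set.seed(8)
  pos <- rbeta(400, 8, 2); neg <- rbeta(2000, 2, 6)
  scores <- c(pos, neg); labels <- rep(c(TRUE, FALSE), c(400, 2000))
  got <- select_threshold(scores, labels, spec_floor = 0.95)
  sweep_grid <- seq(0, 1, by = 1e-4)
  sens <- vapply(sweep_grid, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(sweep_grid, function(t) mean(neg < t), numeric(1))
  best <- max(sens[spec >= 0.95])
  got_sens <- mean(pos >= got$threshold)
  got_spec <- mean(neg < got$threshold)
  expect_gte(got_spec, 0.95)
  expect_gte(got_sens, best - 1e-9)
  expect_error(select_threshold(numeric(0), logical(0)), "no labeled")
})
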