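# Linkage of person clusters to mortality-registry rows by fuzzy name and
# mother's-name matching, with blocking on phonetic keys of the first and
# last name tokens, and linkage-quality evaluation against ground truth.

#' Link mortality-registry rows to person clusters
#'
#' For each death row, candidate clusters are retrieved by phonetic blocking
#' (shared Soundex of either the first or the last name token), scored with
#' [name_similarity()] on names and mother's names, and the best candidate at
#' or above `threshold` is accepted. The combined score is the mean of name
#' and mother scores when both sides carry a mother's name, and the name
#' score alone otherwise. A death row whose mother's name is unusable and
#' which has several perfect name matches is marked `uncertain`, as is an
#' unresolvable tie; uncertain matches count as accepted only when
#' `include_uncertain` is set. Ties at equal combined score prefer the
#' candidate whose last movement precedes the death date.
#'
#' @param clusters tibble from [deduplicate_movements()].
#' @param registry mortality-registry tibble (`row_id`, `name`,
#'   `mother_name`, `death_date`, ...).
#' @param threshold acceptance threshold on the combined score.
#' @param include_uncertain logical sensitivity switch.
#' @param length_exponent passed to [name_similarity()].
#' @param last_movement optional tibble `person_uid`, `last_date` used for
#'   tie-breaking.
#' @param score_floor candidates below this combined score are not reported.
#' @return tibble of match candidates: `death_row_id`, `person_uid`,
#'   `name_score`, `mother_score`, `combined_score`, `status`
#'   (accepted/uncertain/rejected) and `accepted` (logical, reflecting
#'   `include_uncertain`). At most one accepted/uncertain row per death.
#' @export
link_deaths <- function(clusters, registry, threshold = 0.90,
                        include_uncertain = FALSE, length_exponent = 0.5,
                        last_movement = NULL, score_floor = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(registry) == 0) {
    return(tibble(death_row_id = character(), person_uid = character(),
                  name_score = numeric(), mother_score = numeric(),
                  combined_score = numeric(), status = character(),
                  accepted = logical()))
  }
  ckeys <- block_keys(clusters$canonical_name)
  idx1 <- split(seq_len(nrow(clusters)), ckeys$key1)
  idx2 <- split(seq_len(nrow(clusters)), ckeys$key2)
  dkeys <- block_keys(registry$name)
  last_date <- NULL
  if (!is.null(last_movement)) {
    last_date <- setNames(last_movement$last_date, last_movement$person_uid)
  }

  out <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    cand <- unique(c(idx1[[dkeys$key1[i]]], idx2[[dkeys$key1[i]]],
                     idx1[[dkeys$key2[i]]], idx2[[dkeys$key2[i]]]))
    if (length(cand) == 0) next
    ns <- similarity_to_many(registry$name[i],
                             clusters$canonical_name[cand], length_exponent)
    keep <- ns >= score_floor
    cand <- cand[keep]; ns <- ns[keep]
    if (length(cand) == 0) next
    dm <- registry$mother_name[i]
    ms <- rep(NA_real_, length(cand))
    both <- !is.na(dm) & nzchar(dm %||% "") &
      !is.na(clusters$canonical_mother_name[cand])
    if (isTRUE(any(both))) {
      ms[both] <- similarity_to_many(dm,
                                     clusters$canonical_mother_name[cand[both]],
                                     length_exponent)
    }
    comb <- ifelse(is.na(ms), ns, (ns + ms) / 2)
    res <- tibble(death_row_id = registry$row_id[i],
                  person_uid = clusters$person_uid[cand],
                  name_score = ns, mother_score = ms,
                  combined_score = comb, status = "rejected")
    best <- max(comb)
    if (best >= threshold) {
      top <- which(comb == best)
      status <- "accepted"
      if (length(top) > 1 && !is.null(last_date)) {
        ld <- last_date[res$person_uid[top]]
        ok <- !is.na(ld) & ld <= registry$death_date[i]
        if (sum(ok) == 1) top <- top[ok]
      }
      if (length(top) > 1) {
        top <- top[1]
        status <- "uncertain"
      }
      # mother's name unusable and several perfect name matches -> uncertain
      if (all(is.na(res$mother_score[top])) &&
          sum(ns >= 1 - 1e-12) > 1) {
        status <- "uncertain"
      }
      res$status[top] <- status
    }
    out[[i]] <- res
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(death_row_id = character(), person_uid = character(),
                  name_score = numeric(), mother_score = numeric(),
                  combined_score = numeric(), status = character())
  }
  res$accepted <- res$status == "accepted" |
    (include_uncertain & res$status == "uncertain")
  res
}

#' Evaluate linkage quality against ground truth
#'
#' Sensitivity is the proportion of true person-death pairs that were
#' accepted; specificity the proportion of false candidate pairs rejected
#' (computed over the scored candidate pairs); PPV the proportion of accepted
#' pairs that are true. A metric whose denominator is empty is returned as
#' `NA` and named in `undefined`.
#'
#' @param candidates result of [link_deaths()].
#' @param truth_rows truth row-map tibble (`row_id`, `table`, `person_uid`).
#' @param clusters cluster tibble, used to map clusters to true persons by
#'   majority vote over member rows.
#' @param registry the death registry that was linked (defines the universe
#'   of true matches; a registry row whose person never enters the movement
#'   log has no true match).
#' @return one-row tibble: `sensitivity`, `specificity`, `ppv`,
#'   `n_true_pairs`, `n_labeled_pairs`, `undefined` (list-column).
#' @export
evaluate_linkage <- function(candidates, truth_rows, clusters, registry) {
  truth_map <- cluster_truth(clusters, truth_rows)
  death_truth <- truth_rows |> filter(.data$table == "death")
  person_in_log <- unique(truth_map$true_person)

  true_deaths <- death_truth |>
    filter(.data$person_uid %in% person_in_log)
  n_true <- nrow(true_deaths)

  cand <- candidates |>
    left_join(truth_map, by = "person_uid") |>
    left_join(rename(death_truth, true_death_person = "person_uid"),
              by = c("death_row_id" = "row_id")) |>
    mutate(is_true = !is.na(.data$true_person) &
             .data$true_person == .data$true_death_person)

  tp <- sum(cand$accepted & cand$is_true)
  fp <- sum(cand$accepted & !cand$is_true)
  tn <- sum(!cand$accepted & !cand$is_true)
  n_false <- sum(!cand$is_true)

  undefined <- character(0)
  sens <- if (n_true > 0) tp / n_true else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (n_false > 0) tn / n_false else { undefined <- c(undefined, "specificity"); NA_real_ }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "ppv"); NA_real_ }
  if (length(undefined) > 0) {
    warn(paste("undefined linkage metric(s):", paste(undefined, collapse = ", ")))
  }
  tibble(sensitivity = sens, specificity = spec, ppv = ppv,
         n_true_pairs = n_true, n_labeled_pairs = nrow(cand),
         undefined = list(undefined))
}

#' Majority-vote true person behind each cluster
#'
#' @param clusters result of [deduplicate_movements()].
#' @param truth_rows truth row map.
#' @return tibble `person_uid` (cluster), `true_person`.
#' @export
cluster_truth <- function(clusters, truth_rows) {
  cluster_members(clusters) |>
    left_join(truth_rows, by = "row_id",
              suffix = c("", ".truth")) |>
    group_by(person_uid = .data$person_uid) |>
    summarise(true_person = names(sort(table(.data$person_uid.truth),
                                       decreasing = TRUE))[1],
              .groups = "drop")
}

#' Choose an acceptance threshold from labeled scored pairs
#'
#' Sweeps candidate thresholds (midpoints between adjacent distinct scores,
#' plus both extremes) and returns the one maximizing the objective:
#' `"sens_at_spec"` (default) maximizes sensitivity subject to specificity at
#' or above `spec_floor`, falling back to the most specific threshold when
#' the floor is unattainable; `"youden"` maximizes sensitivity + specificity
#' - 1. With perfectly separated classes the midpoint of the gap is
#' returned; if all scores are identical that score is returned with
#' `degenerate = TRUE`.
#'
#' @param scores numeric scores of labeled pairs.
#' @param labels logical; `TRUE` for true pairs.
#' @param objective `"sens_at_spec"` or `"youden"`.
#' @param spec_floor specificity floor for `"sens_at_spec"`.
#' @return list with `threshold`, `metrics` (tibble of the sweep),
#'   `degenerate`.
#' @export
select_threshold <- function(scores, labels,
                             objective = c("sens_at_spec", "youden"),
                             spec_floor = 0.998) {
  objective <- match.arg(objective)
  if (length(scores) == 0) abort("no labeled pairs supplied")
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  us <- sort(unique(scores))
  if (length(us) == 1) {
    return(list(threshold = us, degenerate = TRUE,
                metrics = tibble(threshold = us,
                                 sensitivity = mean(scores[labels] >= us),
                                 specificity = mean(scores[!labels] < us))))
  }
  grid <- c(min(us), (head(us, -1) + tail(us, -1)) / 2, max(us))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  metrics <- tibble(
    threshold = grid,
    sensitivity = vapply(grid, function(th)
      if (n_pos) mean(scores[labels] >= th) else NA_real_, numeric(1)),
    specificity = vapply(grid, function(th)
      if (n_neg) mean(scores[!labels] < th) else NA_real_, numeric(1)))
  pick <- switch(objective,
    sens_at_spec = {
      ok <- which(metrics$specificity >= spec_floor | n_neg == 0)
      if (length(ok) == 0) which.max(metrics$specificity)
      else ok[which.max(metrics$sensitivity[ok])]
    },
    youden = which.max(metrics$sensitivity + metrics$specificity - 1))
  list(threshold = metrics$threshold[pick], metrics = metrics,
       degenerate = FALSE)
}
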