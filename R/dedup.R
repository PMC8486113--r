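# Resolution of unique individuals inside the movement log. Two decision
# trees, mirroring how administrative prison logs go wrong:
#   (A) one internal ID carries several name spellings -> merge spellings
#       whose similarity clears the name threshold, split otherwise;
#   (B) several internal IDs carry the same or similar names -> merge only
#       when the mother's names also agree; a missing mother's name routes
#       the pair to the uncertain branch (merged only on request).

#' Resolve unique individuals in a movement log
#'
#' @param log movement-log tibble with columns `row_id`, `internal_id`,
#'   `name`, `mother_name` (and optionally `sex`).
#' @param name_threshold minimum [name_similarity()] for two spellings to be
#'   the same person.
#' @param mother_threshold minimum mother's-name similarity for a cross-ID
#'   merge.
#' @param merge_uncertain merge cross-ID name matches whose mother's name is
#'   missing on either side (default keeps them separate).
#' @param length_exponent passed to [name_similarity()].
#' @return tibble with one row per person cluster: `person_uid`,
#'   `canonical_name`, `canonical_mother_name`, `sex`, `n_rows`, and a
#'   list-column `member_row_ids`. Clusters partition the input rows.
#' @export
deduplicate_movements <- function(log, name_threshold = 0.85,
                                  mother_threshold = 0.85,
                                  merge_uncertain = FALSE,
                                  length_exponent = 0.5) {
  if (nrow(log) == 0) abort("movement log is empty")

  # --- tree A: within internal_id, single-link clustering of name variants
  log$._unit <- NA_integer_
  unit_n <- 0L
  idx_by_id <- split(seq_len(nrow(log)), log$internal_id)
  for (rows in idx_by_id) {
    nms <- log$name[rows]
    uniq <- unique(nms)
    if (length(uniq) == 1) {
      grp <- rep(1L, length(rows))
    } else {
      # single-link components over the name-variant similarity graph
      k <- length(uniq)
      parent <- seq_len(k)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(k - 1)) {
        sims <- similarity_to_many(uniq[i], uniq[(i + 1):k], length_exponent)
        for (j in which(sims >= name_threshold)) {
          ri <- find(i); rj <- find(i + j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      comp <- vapply(seq_len(k), find, integer(1))
      grp <- comp[match(nms, uniq)]
    }
    for (g in unique(grp)) {
      unit_n <- unit_n + 1L
      log$._unit[rows[grp == g]] <- unit_n
    }
  }

  # canonical attributes per unit: modal name, modal non-missing mother
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_character_)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  units <- log |>
    group_by(.data$._unit) |>
    summarise(canonical_name = modal(.data$name),
              canonical_mother_name = modal(.data$mother_name),
              sex = if ("sex" %in% names(log)) modal(.data$sex)
                    else NA_character_,
              .groups = "drop")

  # --- tree B: merge units across internal IDs
  nu <- nrow(units)
  parent <- seq_len(nu)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keys <- block_keys(units$canonical_name)
  blk <- paste(keys$key1, keys$key2)
  blocks <- split(seq_len(nu), blk)
  blocks <- blocks[lengths(blocks) > 1]
  for (members in blocks) {
    k <- length(members)
    for (ii in seq_len(k - 1)) {
      i <- members[ii]
      rest <- members[(ii + 1):k]
      nsim <- similarity_to_many(units$canonical_name[i],
                                 units$canonical_name[rest], length_exponent)
      cand <- rest[nsim >= name_threshold]
      if (length(cand) == 0) next
      msim <- similarity_to_many(units$canonical_mother_name[i],
                                 units$canonical_mother_name[cand],
                                 length_exponent)
      mother_known <- !is.na(units$canonical_mother_name[i]) &
        !is.na(units$canonical_mother_name[cand])
      do_merge <- (mother_known & msim >= mother_threshold) |
        (!mother_known & merge_uncertain)
      for (j in cand[do_merge]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(nu), find, integer(1))
  cluster_of_unit <- match(comp, sort(unique(comp)))
  log$._cluster <- cluster_of_unit[log$._unit]

  clusters <- log |>
    group_by(.data$._cluster) |>
    summarise(canonical_name = modal(.data$name),
              canonical_mother_name = modal(.data$mother_name),
              sex = if ("sex" %in% names(log)) modal(.data$sex)
                    else NA_character_,
              n_rows = dplyr::n(),
              member_row_ids = list(.data$row_id),
              .groups = "drop") |>
    mutate(person_uid = sprintf("C%06d", .data$._cluster)) |>
    select("person_uid", "canonical_name", "canonical_mother_name",
           "sex", "n_rows", "member_row_ids")
  clusters
}

#' Long membership table of a cluster set
#'
#' @param clusters result of [deduplicate_movements()].
#' @return tibble with columns `person_uid`, `row_id`.
#' @export
cluster_members <- function(clusters) {
  tidyr::unnest(select(clusters, "person_uid", "member_row_ids"),
                "member_row_ids") |>
    rename(row_id = "member_row_ids")
}
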