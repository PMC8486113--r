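# ICD-10 underlying-cause grouping into intermediate and broad public-health
# categories. The mapping ships as data (inst/extdata/cause_map.csv), one row
# per ICD-10 three-character range in priority order: the first matching row
# wins, and anything unmatched falls into an explicit default bucket so the
# mapping is total.

# intermediate composition of each broad category used when *generating*
# synthetic deaths; codes drawn from ICD_EXAMPLES round-trip through the
# bundled mapping back to the same broad category (asserted in tests)
INTERMEDIATE_MIX <- list(
  violence = c(interpersonal_violence = 1),
  suicide = c(suicide = 1),
  communicable = c(tuberculosis = 0.30, hiv_aids = 0.20,
                   respiratory_infection = 0.30, other_communicable = 0.20),
  noncommunicable = c(cardiovascular = 0.40, neoplasm = 0.30, diabetes = 0.10,
                      drug_overdose = 0.05, other_noncommunicable = 0.15),
  transport = c(transport_injury = 1),
  other_unknown = c(ill_defined = 0.7, undetermined_intent = 0.3)
)

ICD_EXAMPLES <- list(
  interpersonal_violence = c("X93", "X95", "Y00", "X99"),
  suicide = c("X70", "X68", "X80", "X64"),
  tuberculosis = c("A15", "A16", "A19"),
  hiv_aids = c("B20", "B22", "B24"),
  respiratory_infection = c("J18", "J15", "J22"),
  other_communicable = c("A41", "B19", "G00"),
  cardiovascular = c("I21", "I64", "I10", "I50"),
  neoplasm = c("C34", "C16", "C61", "C50"),
  diabetes = c("E11", "E14"),
  drug_overdose = c("X42", "X44"),
  other_noncommunicable = c("K70", "N18", "J44"),
  transport_injury = c("V23", "V43", "V89", "V09"),
  ill_defined = c("R99", "R98"),
  undetermined_intent = c("Y34", "Y24")
)

#' Load the bundled ICD-10 cause mapping table
#'
#' @param path optional path to an alternative mapping CSV with columns
#'   `icd_low`, `icd_high`, `intermediate`, `broad` (rows in priority order).
#' @return tibble of the mapping, with numeric range keys attached.
#' @export
load_cause_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cause_map.csv",
                                package = "carcmort", mustWork = TRUE)
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  map$key_low <- icd_key(map$icd_low)
  map$key_high <- icd_key(map$icd_high)
  as_tibble(map)
}

# numeric rank of a three-character ICD-10 category: letter block * 100 + number
icd_key <- function(code) {
  code <- toupper(sub("\\..*$", "", code))
  bad <- !grepl("^[A-Z][0-9]{2}$", code) & !is.na(code)
  if (any(bad)) {
    abort(paste0("malformed ICD-10 code(s): ",
                 paste(unique(code[bad]), collapse = ", ")),
          class = "carcmort_icd_error")
  }
  (match(substr(code, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(code, 2, 3))
}

#' Map ICD-10 underlying causes to intermediate and broad categories
#'
#' Deterministic lookup over the bundled range table, with two special rules:
#' codes for hanging, strangulation and suffocation of undetermined intent
#' (Y20) are classified as interpersonal violence for in-custody deaths of
#' men; absent codes, "other ill-defined and unspecified causes" (R99) and
#' "unspecified event, undetermined intent" (Y34) are of unknown cause (they
#' land in the `other_unknown` broad category).
#'
#' @param code character vector of ICD-10 codes (`NA` allowed).
#' @param in_custody logical, recycled: was the death in custody?
#' @param sex character, recycled.
#' @param map mapping table from [load_cause_map()].
#' @param y20_rule set `FALSE` to disable the in-custody Y20 reassignment
#'   (sensitivity analysis).
#' @return tibble with columns `icd10_code`, `intermediate_cause`,
#'   `broad_cause`.
#' @export
map_icd10 <- function(code, in_custody = FALSE, sex = NA_character_,
                      map = load_cause_map(), y20_rule = TRUE) {
  n <- length(code)
  in_custody <- rep_len(in_custody, n)
  sex <- rep_len(sex, n)
  key <- rep(NA_integer_, n)
  present <- !is.na(code) & nzchar(code)
  key[present] <- icd_key(code[present])

  inter <- rep("no_record", n)
  broad <- rep("other_unknown", n)
  if (any(present)) {
    km <- vapply(key[present], function(k) {
      hit <- which(map$key_low <= k & map$key_high >= k)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
    inter[present] <- if_else(is.na(km), "unlisted",
                              map$intermediate[km])
    broad[present] <- if_else(is.na(km), "noncommunicable", map$broad[km])
  }
  if (y20_rule) {
    y20 <- !is.na(key) & key %/% 100 == match("Y", LETTERS) - 1L &
      key %% 100 == 20L & in_custody & !is.na(sex) & sex == "male"
    inter[y20] <- "interpersonal_violence"
    broad[y20] <- "violence"
  }
  tibble(icd10_code = code, intermediate_cause = inter, broad_cause = broad)
}

#' Tabulate cause-of-death assignments by strata
#'
#' @param assignments tibble containing a `broad_cause` column plus any
#'   stratum columns.
#' @param strata character vector of stratum column names (may be empty).
#' @return tibble of `n` and within-stratum `proportion` per broad cause.
#' @export
tabulate_causes <- function(assignments, strata = character()) {
  grp <- c(strata, "broad_cause")
  out <- assignments |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(n = dplyr::n(), .groups = "drop")
  if (length(strata) > 0) {
    out <- out |>
      group_by(across(dplyr::all_of(strata))) |>
      mutate(proportion = .data$n / sum(.data$n)) |>
      ungroup()
  } else {
    out$proportion <- out$n / sum(out$n)
  }
  out
}
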