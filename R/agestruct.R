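# Disaggregation of wide-binned age structure into single-year-of-age masses
# by maximum-likelihood fitting of a truncated negative binomial, adjustment
# of the fitted masses to reproduce the reported bin proportions exactly,
# cohort aging, death subtraction, and construction of the non-incarcerated
# person-time denominator by subtraction.

#' Fit a truncated negative binomial to wide-binned age data
#'
#' Parameters (size, mean) maximize the multinomial likelihood of the
#' reported bin proportions under a negative binomial truncated (by
#' renormalization) to the integer ages `bounds[1]..bounds[2]`. Optimization
#' is derivative-free Nelder-Mead on the log scale from several starting
#' points; tolerance 1e-8 on the log-likelihood.
#'
#' @param binned tibble with `age_low`, `age_high`, `proportion` (at least 3
#'   bins with positive mass).
#' @param bounds integer truncation bounds (years of age).
#' @return list with `params` (size, mu, bounds, logLik, convergence) and
#'   `fine` (tibble `age`, `proportion` summing to 1).
#' @export
fit_truncated_negbin <- function(binned, bounds = c(18L, 95L)) {
  binned <- validate_binned_age_table(binned)
  if (sum(binned$proportion > 0) < 3) {
    abort("need at least 3 bins with positive mass to fit an age distribution",
          class = "carcmort_fit_error")
  }
  ages <- seq.int(bounds[1], bounds[2])
  bin_of <- findInterval(ages, binned$age_low)
  bin_of[ages > max(binned$age_high)] <- nrow(binned)
  bin_of[bin_of < 1L] <- 1L

  nll <- function(par) {
    size <- exp(par[1]); mu <- exp(par[2])
    dens <- dnbinom(ages, size = size, mu = mu)
    z <- sum(dens)
    if (!is.finite(z) || z <= 0) return(1e10)
    pbin <- tapply(dens / z, bin_of, sum)
    pbin <- pbin[as.character(seq_len(nrow(binned)))]
    pbin[is.na(pbin)] <- 0
    ll <- sum(binned$proportion * log(pmax(pbin, 1e-300)))
    -ll
  }
  mean0 <- sum(binned$proportion * (binned$age_low + binned$age_high) / 2)
  starts <- list(c(log(5), log(mean0)), c(log(1), log(mean0)),
                 c(log(20), log(mean0 * 0.8)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 5000))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (best$convergence != 0) {
    abort(sprintf(paste0("truncated negative binomial fit did not converge ",
                         "(code %d, nll %.6f, par %.4f/%.4f)"),
                  best$convergence, best$value, best$par[1], best$par[2]),
          class = "carcmort_fit_error")
  }
  size <- exp(best$par[1]); mu <- exp(best$par[2])
  dens <- dnbinom(ages, size = size, mu = mu)
  fine <- tibble(age = ages, proportion = dens / sum(dens))
  list(params = list(size = size, mu = mu, lower = bounds[1],
                     upper = bounds[2], logLik = -best$value,
                     convergence = best$convergence),
       fine = fine)
}

#' Rescale a fine age distribution to match reported bin proportions
#'
#' Within each wide bin the fine masses are multiplied by a single factor so
#' that bin totals equal the reported proportions exactly; ages outside every
#' bin get mass 0. The output sums to 1 when the reported proportions do.
#'
#' @param fine tibble `age`, `proportion`.
#' @param binned tibble `age_low`, `age_high`, `proportion`.
#' @return adjusted fine tibble.
#' @export
adjust_to_bins <- function(fine, binned) {
  binned <- arrange(binned, .data$age_low)
  out <- fine
  out$proportion <- 0
  for (i in seq_len(nrow(binned))) {
    sel <- fine$age >= binned$age_low[i] & fine$age <= binned$age_high[i]
    tot <- sum(fine$proportion[sel])
    if (binned$proportion[i] > 0 && tot <= 0) {
      abort(sprintf("no fitted mass in bin %d-%d with reported proportion %g",
                    binned$age_low[i], binned$age_high[i],
                    binned$proportion[i]),
            class = "carcmort_fit_error")
    }
    if (tot > 0) {
      out$proportion[sel] <- fine$proportion[sel] *
        (binned$proportion[i] / tot)
    }
  }
  out
}

#' Age a fine distribution forward
#'
#' Mass at age a moves to a + years; mass shifted beyond the top age of the
#' support accumulates in the top age. Total mass is conserved.
#'
#' @param fine tibble `age`, `proportion`.
#' @param years non-negative integer shift.
#' @return shifted fine tibble on the same support.
#' @export
age_forward <- function(fine, years) {
  stopifnot(years >= 0, years == floor(years))
  if (years == 0) return(fine)
  top <- max(fine$age)
  new_age <- pmin(fine$age + years, top)
  out <- tibble(age = fine$age, proportion = 0)
  agg <- tapply(fine$proportion, new_age, sum)
  out$proportion[match(as.integer(names(agg)), out$age)] <- as.numeric(agg)
  out
}

#' Four-year standardization bins
#'
#' @param start first age; @param width bin width; @param top lower bound of
#'   the open-ended last bin; @param max_age top age closing the last bin.
#' @return tibble `age_bin` (label), `age_low`, `age_high`.
#' @export
age_bins_4yr <- function(start = 18, width = 4, top = 62, max_age = 95) {
  lows <- seq(start, top, by = width)
  highs <- c(lows[-1] - 1, max_age)
  tibble(age_bin = sprintf("%d-%d", lows, highs),
         age_low = lows, age_high = highs)
}

assign_age_bin <- function(age, bins = age_bins_4yr()) {
  idx <- findInterval(pmin(age, max(bins$age_high)), bins$age_low)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= min(bins$age_low)
  out[ok] <- bins$age_bin[idx[ok]]
  out
}

#' Allocate unstratified person-time over ages with a fine distribution
#'
#' @param person_years scalar person-years of a cell.
#' @param fine fine age distribution for that cell.
#' @param bins standardization bins from [age_bins_4yr()].
#' @return tibble `age_bin`, `person_years`; sums to the input total.
#' @export
allocate_person_time_by_age <- function(person_years, fine,
                                        bins = age_bins_4yr()) {
  fine$age_bin <- assign_age_bin(fine$age, bins)
  fine |>
    filter(!is.na(.data$age_bin)) |>
    group_by(.data$age_bin) |>
    summarise(mass = sum(.data$proportion), .groups = "drop") |>
    mutate(person_years = person_years * .data$mass / sum(.data$mass)) |>
    select("age_bin", "person_years")
}

#' Subtract decedents' foregone person-time from age-stratified cells
#'
#' @param py tibble with stratum columns, `age_bin` and `person_years`.
#' @param deaths tibble with the same stratum columns plus `deaths`; deaths
#'   are assumed to occur a fraction `fraction_elapsed` of the way through a
#'   cell of width `cell_years`, so each decedent foregoes
#'   `(1 - fraction_elapsed) * cell_years` person-years.
#' @param fraction_elapsed,cell_years see above.
#' @return `py` with reduced `person_years`, floored at 0 (with a warning
#'   when flooring occurs).
#' @export
subtract_deaths <- function(py, deaths, fraction_elapsed = 0.5,
                            cell_years = 1) {
  if (nrow(deaths) == 0 || sum(deaths$deaths) == 0) return(py)
  keys <- setdiff(intersect(names(py), names(deaths)), "person_years")
  out <- left_join(py, deaths, by = keys)
  out$deaths[is.na(out$deaths)] <- 0
  adj <- out$person_years - out$deaths * (1 - fraction_elapsed) * cell_years
  if (any(adj < -1e-9)) {
    warn("death subtraction drove person-time below zero; flooring at 0")
  }
  out$person_years <- pmax(0, adj)
  out$deaths <- NULL
  out
}

#' Non-incarcerated person-time by subtraction
#'
#' General-population person-time minus custody person-time minus
#' formerly-incarcerated person-time (the latter computed from releases from
#' any facility type). Cells are matched on the shared stratum columns;
#' negative results are floored at 0 with a warning.
#'
#' @param projected_py tibble of general-population person-years with
#'   stratum columns and `person_years`.
#' @param incarcerated_py,former_py same shape.
#' @return tibble like `projected_py`.
#' @export
non_incarcerated_denominator <- function(projected_py, incarcerated_py,
                                         former_py) {
  keys <- setdiff(names(projected_py), "person_years")
  sub1 <- incarcerated_py |>
    group_by(across(dplyr::all_of(intersect(keys, names(incarcerated_py))))) |>
    summarise(inc_py = sum(.data$person_years), .groups = "drop")
  sub2 <- former_py |>
    group_by(across(dplyr::all_of(intersect(keys, names(former_py))))) |>
    summarise(frm_py = sum(.data$person_years), .groups = "drop")
  out <- projected_py |>
    left_join(sub1, by = intersect(keys, names(sub1))) |>
    left_join(sub2, by = intersect(keys, names(sub2)))
  out$inc_py[is.na(out$inc_py)] <- 0
  out$frm_py[is.na(out$frm_py)] <- 0
  res <- out$person_years - out$inc_py - out$frm_py
  if (any(res < -1e-9)) {
    warn("denominator subtraction drove person-time below zero; flooring at 0")
  }
  out$person_years <- pmax(0, res)
  out$inc_py <- NULL
  out$frm_py <- NULL
  out
}
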