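#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n row_number across
#'   if_else case_when rename distinct pull slice count tally transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom stats optim rexp runif rbinom qbeta qchisq qgamma qf rpois
#'   dnbinom pnbinom setNames aggregate quantile
#' @importFrom utils adist head tail
NULL

DAYS_PER_YEAR <- 365.25

#' Convert a day count to person-years
#' @param days numeric vector of day counts
#' @return numeric person-years (days / 365.25)
#' @export
days_to_years <- function(days) days / DAYS_PER_YEAR

years_to_days <- function(years) years * DAYS_PER_YEAR

# fractional years between two Dates, half-open [start, end)
interval_years <- function(start, end) {
  as.numeric(end - start) / DAYS_PER_YEAR
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "carcmort_config_error")
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(field, "probabilities must lie in [0, 1]")
  }
  invisible(x)
}

check_rate <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_config(field, "rates must be finite and >= 0")
  }
  invisible(x)
}

FACILITY_TYPES <- c("closed", "semi_open", "police", "youth")
LOCATIONS <- c(FACILITY_TYPES, "post_release")
STATES <- c("free_never", FACILITY_TYPES, "post_release", "free_other")
BROAD_CAUSES <- c("violence", "suicide", "communicable", "noncommunicable",
                  "transport", "other_unknown")
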