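#' Forest-style plot of standardized rates or rate ratios
#'
#' @param rates the `rates` tibble of a [run_pipeline()] result.
#' @param what `"irr"` (rate ratios, log scale, reference line at 1) or
#'   `"rate"` (standardized rates per 100,000).
#' @param cause broad cause to display.
#' @return ggplot object.
#' @export
plot_rates <- function(rates, what = c("irr", "rate"), cause = "all") {
  what <- match.arg(what)
  d <- filter(rates, .data$cause == !!cause)
  if (what == "irr") {
    d <- filter(d, !is.na(.data$irr))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$irr,
                                         y = .data$population,
                                         color = .data$sex)) +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$irr_low, xmax = .data$irr_high),
        height = 0.15, position = ggplot2::position_dodge(0.4)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "standardized incidence rate ratio (95% CI)",
                    y = NULL)
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rate_per_100k,
                                         y = .data$population,
                                         color = .data$sex)) +
      ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
        height = 0.15, position = ggplot2::position_dodge(0.4)) +
      ggplot2::labs(x = "deaths per 100,000 person-years (95% CI)",
                    y = NULL)
  }
  p + ggplot2::theme_minimal()
}

#' Step plot of one or more Kaplan-Meier curves
#'
#' @param ... named [km_estimate()] tibbles.
#' @return ggplot object.
#' @export
plot_km <- function(...) {
  curves <- list(...)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  d <- bind_rows(lapply(names(curves), function(nm) {
    mutate(curves[[nm]], group = nm)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(NA, 1)) +
    ggplot2::labs(x = "years since release", y = "survival") +
    ggplot2::theme_minimal()
}

#' Tidy the rate table of a pipeline run
#' @param x `carcmort_run` object.
#' @param ... unused.
#' @return the `rates` tibble.
#' @export
tidy.carcmort_run <- function(x, ...) x$rates

#' One-row summary of a pipeline run
#' @param x `carcmort_run` object.
#' @param ... unused.
#' @return tibble of the headline manifest counts.
#' @export
glance.carcmort_run <- function(x, ...) {
  m <- x$manifest
  tibble(n_movement_rows = m$n_movement_rows, n_persons = m$n_clusters,
         n_registry_rows = m$n_registry_rows, n_linked = m$n_accepted,
         deaths_custody = m$deaths_custody,
         deaths_post_release = m$deaths_post_release,
         person_years_custody = sum(unlist(m$person_years_custody)),
         person_years_post_release = m$person_years_post_release,
         linkage_threshold = m$threshold, seed = m$seed)
}
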