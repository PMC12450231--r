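#' Tidy a simulation run
#'
#' Long-format per-tick, per-region series: one row per (tick, region,
#' metric).
#'
#' @param x A `coop_run`.
#' @param ... Unused.
#' @return A tibble with columns `tick`, `region`, `metric`, `value`.
#' @method tidy coop_run
#' @export
tidy.coop_run <- function(x, ...) {
  tidyr::pivot_longer(x$series, cols = -c("tick", "region"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a simulation run
#'
#' @param x A `coop_run`.
#' @param ... Unused.
#' @return A tibble with the scenario, ticks run, final population,
#'   final cooperator share (among trait-bearing adults, both regions
#'   pooled), extinction flag and tick.
#' @method glance coop_run
#' @export
glance.coop_run <- function(x, ...) {
  fin <- x$series[x$series$tick == max(x$series$tick), ]
  nc <- sum(fin$cooperators); nd <- sum(fin$defectors)
  tibble::tibble(
    scenario = x$config$scenario,
    ticks = x$ticks_run,
    final_population = sum(fin$population),
    final_cooperator_share = if (nc + nd > 0) nc / (nc + nd) else NA_real_,
    extinct = x$extinct,
    extinction_tick = x$extinction_tick,
    seed = x$seed %||% NA_integer_
  )
}

#' Plot the population dynamics of a run
#'
#' Cooperators, defectors and total population over time, faceted by region.
#'
#' @param object A `coop_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coop_run
#' @export
autoplot.coop_run <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$series[, c("tick", "region", "population", "cooperators",
                      "defectors")],
    cols = c("population", "cooperators", "defectors"),
    names_to = "series", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tick, y = .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "tick (months)", y = "agents", colour = NULL)
}

#' Export a run's series as tidy CSV
#'
#' @param x A `coop_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(x, path) {
  readr::write_csv(tidy.coop_run(x), path)
  invisible(path)
}
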