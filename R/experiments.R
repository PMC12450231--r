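#' Factorial experiment plan
#'
#' Enumerates the full factor grid explored in the study design:
#' initial cooperation probability x conformist-transmission strength x
#' cooperation cost x climate scenario (3 x 3 x 3 x 4 = 108 cells), with a
#' fixed number of repetitions per cell. Each (cell, repetition) receives a
#' seed that is a pure function of the base seed and the indices.
#'
#' @param prob_cooperation,alpha,cost Factor levels (defaults are the
#'   published ranges 0.2/0.5/0.8, 0.2/0.5/0.8 and 10/20/50).
#' @param scenarios Scenario levels (all four by default).
#' @param repetitions Repetitions per cell (default 3).
#' @param base_seed Base seed for the seed schedule.
#' @return A `coop_plan` tibble with one row per run: `cell`, `rep`,
#'   the factor columns, and `seed`.
#' @export
#' @examples
#' nrow(experiment_plan())  # 324 runs
experiment_plan <- function(prob_cooperation = c(0.2, 0.5, 0.8),
                            alpha = c(0.2, 0.5, 0.8),
                            cost = c(10, 20, 50),
                            scenarios = c("S1", "S2", "S3", "S4"),
                            repetitions = 3L,
                            base_seed = 1L) {
  cells <- tidyr::expand_grid(
    prob_cooperation = prob_cooperation, alpha = alpha, cost = cost,
    scenario = scenarios
  )
  cells$cell <- seq_len(nrow(cells))
  plan <- tidyr::expand_grid(cells, rep = seq_len(repetitions))
  plan$seed <- seed_for(base_seed, plan$cell, plan$rep)
  plan <- plan[, c("cell", "rep", "prob_cooperation", "alpha", "cost",
                   "scenario", "seed")]
  class(plan) <- c("coop_plan", class(plan))
  attr(plan, "base_seed") <- base_seed
  plan
}

# Seed schedule: a pure function of (base seed, cell, repetition), unique for
# any plan with fewer than 1000 repetitions per cell, kept below 2^31.
seed_for <- function(base_seed, cell, rep) {
  as.integer((base_seed + cell * 1000L + rep) %% .Machine$integer.max)
}

#' Run a factorial sweep
#'
#' Runs every (cell, repetition) of the plan with the cell's factors patched
#' into the base configuration, and aggregates the population series across
#' repetitions into per-tick bands (mean, sd, min, max). Results are
#' independent of execution order because each run draws only from its own
#' seeded stream. A failed run is recorded in `failures` with a warning,
#' never silently dropped.
#'
#' @param plan A [experiment_plan()] tibble (or any tibble with its columns).
#' @param config_base Base [coop_config()]; cell factors override
#'   `prob_cooperation`, `alpha`, `cost` and `scenario`.
#' @param keep_runs Keep each run's per-tick series (needed to re-derive the
#'   bands; default `TRUE`).
#' @return A `coop_sweep`: list with `summary` (per cell, tick, region bands
#'   for population, cooperators, defectors), `outcomes_raw` (per-run
#'   glances), `runs` (per-run series if kept), `plan`, `failures`.
#' @export
run_sweep <- function(plan, config_base = coop_config(), keep_runs = TRUE) {
  stopifnot(all(c("cell", "rep", "prob_cooperation", "alpha", "cost",
                  "scenario", "seed") %in% names(plan)))
  runs <- vector("list", nrow(plan))
  glances <- vector("list", nrow(plan))
  failures <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cfg <- config_base
    cfg$prob_cooperation <- row$prob_cooperation
    cfg$alpha <- row$alpha
    cfg$cost <- row$cost
    cfg$scenario <- row$scenario
    sdef <- scenario_defaults(row$scenario)
    cfg$cooling_rate <- sdef$cooling_rate
    cfg$base_energy_cost <- sdef$base_energy_cost
    cfg$cap_multiplier <- sdef$cap_multiplier
    res <- tryCatch(run_simulation(cfg, seed = row$seed), error = identity)
    if (inherits(res, "error")) {
      warning("run ", i, " (cell ", row$cell, ", rep ", row$rep,
              ") failed: ", conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        tibble::tibble(cell = row$cell, rep = row$rep,
                       message = conditionMessage(res))
      next
    }
    ser <- res$series[, c("tick", "region", "population", "cooperators",
                          "defectors")]
    ser$cell <- row$cell
    ser$rep <- row$rep
    runs[[i]] <- ser
    g <- glance.coop_run(res)
    g$cell <- row$cell
    g$rep <- row$rep
    # per-region finals for outcome tables
    fin <- res$series[res$series$tick == max(res$series$tick), ]
    g <- tidyr::expand_grid(g, region = .regions)
    g$final_population_region <- fin$population[match(g$region, fin$region)]
    g$final_cooperators_region <- fin$cooperators[match(g$region, fin$region)]
    g$final_defectors_region <- fin$defectors[match(g$region, fin$region)]
    glances[[i]] <- g
    runs[[i]] <- ser
  }
  run_series <- dplyr::bind_rows(runs)
  summary <- run_series |>
    tidyr::pivot_longer(cols = c("population", "cooperators", "defectors"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$cell, .data$tick, .data$region, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      n = dplyr::n(), .groups = "drop"
    )
  structure(
    list(summary = summary,
         outcomes_raw = dplyr::bind_rows(glances),
         runs = if (keep_runs) run_series else NULL,
         plan = plan,
         failures = dplyr::bind_rows(failures)),
    class = "coop_sweep"
  )
}

#' @export
print.coop_sweep <- function(x, ...) {
  cat("<coop_sweep>", length(unique(x$plan$cell)), "cells x",
      max(x$plan$rep), "repetitions;", nrow(x$failures), "failures\n")
  invisible(x)
}

#' Outcome table of a sweep
#'
#' Per cell and region, averaged over repetitions: final population, final
#' cooperator share, the fraction of repetitions ending in extinction, and
#' the mean extinction tick among extinct repetitions.
#'
#' @param sweep A [run_sweep()] result.
#' @return A tibble, one row per (cell, region), joined with the cell's
#'   factor levels.
#' @export
summarize_outcomes <- function(sweep) {
  stopifnot(inherits(sweep, "coop_sweep"))
  cells <- dplyr::distinct(sweep$plan[, c("cell", "prob_cooperation",
                                          "alpha", "cost", "scenario")])
  out <- sweep$outcomes_raw |>
    dplyr::group_by(.data$cell, .data$region) |>
    dplyr::summarise(
      final_population = mean(.data$final_population_region),
      final_cooperators = mean(.data$final_cooperators_region),
      final_defectors = mean(.data$final_defectors_region),
      final_cooperator_share = {
        nc <- sum(.data$final_cooperators_region)
        nd <- sum(.data$final_defectors_region)
        if (nc + nd > 0) nc / (nc + nd) else NA_real_
      },
      extinction_rate = mean(.data$extinct),
      extinction_tick = if (any(.data$extinct))
        mean(.data$extinction_tick[.data$extinct]) else NA_real_,
      .groups = "drop"
    )
  dplyr::left_join(cells, out, by = "cell")
}

#' Plot sweep bands
#'
#' Mean population with one-standard-deviation (dark) and min-max (light)
#' ribbons across repetitions, faceted by region, for the selected cells.
#'
#' @param object A `coop_sweep`.
#' @param cells Cell ids to show (default: all).
#' @param metric One of `"population"`, `"cooperators"`, `"defectors"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coop_sweep
#' @export
autoplot.coop_sweep <- function(object, cells = NULL, metric = "population",
                                ...) {
  df <- object$summary[object$summary$metric == metric, ]
  if (!is.null(cells)) df <- df[df$cell %in% cells, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tick, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cell ~ region) +
    ggplot2::labs(x = "tick (months)", y = metric)
}
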