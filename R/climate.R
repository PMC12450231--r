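#' Climate forcing table for the four scenarios
#'
#' Returns the bundled per-scenario, per-region climate forcing used by the
#' simulator: one annual mean used at initialization (the "setup" value) and
#' four quarterly means (winter, spring, summer, autumn) that drive the run.
#' Scenarios S2 (glacial high seasonality) and S3 (interglacial high
#' seasonality) share a single quarterly row; they differ only in their setup
#' means and in non-climate costs.
#'
#' Temperatures are in degrees Celsius. S1 is the mild glacial-interglacial
#' average, S2/S3 the coldest-quarter scenarios, S4 the warmest-quarter
#' (arid, resource-limited) scenario.
#'
#' @return A tibble with columns `scenario`, `region`, `setup`, `winter`,
#'   `spring`, `summer`, `autumn`.
#' @export
#' @examples
#' climate_table()
climate_table <- function() {
  tibble::tribble(
    ~scenario, ~region,    ~setup, ~winter, ~spring, ~summer, ~autumn,
    "S1",      "TianShan",  6,      -0.98,   11.26,   24.42,   12.35,
    "S1",      "Altai",    -4,     -16.4,     2.60,   19.37,    3.97,
    "S2",      "TianShan", -7,      -7,       7.29,   19.20,    4.95,
    "S2",      "Altai",    -21.5,  -20,      -4.42,   11.54,   -2.92,
    "S3",      "TianShan", -9.6,    -7,       7.29,   19.20,    4.95,
    "S3",      "Altai",    -20,    -20,      -4.42,   11.54,   -2.92,
    "S4",      "TianShan", 25,       3.67,   16.64,   31.59,   18.76,
    "S4",      "Altai",     19.4,  -10.05,    9.83,   27.18,   10.88
  )
}

#' Build the climate schedule for one scenario
#'
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return An object of class `coop_schedule`: the scenario label, a named
#'   vector of setup (initialization) temperatures per region, and a
#'   region-by-season matrix of quarterly temperatures.
#' @export
#' @examples
#' sched <- scenario_schedule("S1")
#' temperature_at(sched, "TianShan", tick = 0)
scenario_schedule <- function(scenario = c("S1", "S2", "S3", "S4")) {
  scenario <- match.arg(scenario)
  tab <- climate_table()
  tab <- tab[tab$scenario == scenario, ]
  quarterly <- as.matrix(tab[, .seasons])
  rownames(quarterly) <- tab$region
  structure(
    list(
      scenario = scenario,
      setup = setNames(tab$setup, tab$region),
      quarterly = quarterly
    ),
    class = "coop_schedule"
  )
}

#' @export
print.coop_schedule <- function(x, ...) {
  cat("<coop_schedule> scenario", x$scenario, "\n")
  cat("setup (deg C):", paste(names(x$setup), x$setup, collapse = ", "), "\n")
  print(x$quarterly)
  invisible(x)
}

#' Season of a tick
#'
#' One tick is one month; the season advances every `season_length` ticks and
#' cycles winter, spring, summer, autumn (12 ticks = one year).
#'
#' @param tick Month index from 0 (vectorized).
#' @param start_season Season at tick 0.
#' @param season_length Ticks per season (default 3).
#' @return Character vector of season names.
#' @export
#' @examples
#' season_of(c(0, 3, 11, 12))
season_of <- function(tick, start_season = "winter", season_length = 3) {
  stopifnot(all(tick >= 0), season_length >= 1)
  offset <- match(match.arg(start_season, .seasons), .seasons) - 1L
  .seasons[((tick %/% season_length + offset) %% 4L) + 1L]
}

#' Quarterly forcing temperature at a tick
#'
#' Returns the exact tabulated quarterly mean for the region and the season of
#' `tick`; no interpolation is applied.
#'
#' @param schedule A [scenario_schedule()] object.
#' @param region `"TianShan"` or `"Altai"`.
#' @param tick Month index from 0.
#' @param start_season Season at tick 0.
#' @return Temperature in degrees Celsius.
#' @export
temperature_at <- function(schedule, region, tick, start_season = "winter") {
  stopifnot(inherits(schedule, "coop_schedule"))
  if (!all(region %in% rownames(schedule$quarterly))) {
    stop("unknown region: ", paste(setdiff(region, rownames(schedule$quarterly)),
                                   collapse = ", "))
  }
  season <- season_of(tick, start_season)
  schedule$quarterly[cbind(region, season)]
}

#' Setup-phase mean temperature
#'
#' The annual mean used only at initialization (tick-0 diagnostics); quarterly
#' values drive the run itself.
#'
#' @inheritParams temperature_at
#' @return Temperature in degrees Celsius.
#' @export
setup_temperature <- function(schedule, region) {
  stopifnot(inherits(schedule, "coop_schedule"))
  if (!all(region %in% names(schedule$setup))) {
    stop("unknown region: ", paste(setdiff(region, names(schedule$setup)),
                                   collapse = ", "))
  }
  schedule$setup[region]
}
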