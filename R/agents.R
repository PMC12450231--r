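# Agent state lives in a data frame with one row per agent:
#   id, x, y (patch-center coordinates), origin (region at birth), energy,
#   body_temp, age (years, +1/12 per tick), trait (1 cooperate / 0 defect /
#   NA juvenile), knows_path, target (shelter id), dest_x/dest_y (migration
#   destination), low_res_ticks (depleted-patch counter), alive, death_cause.

#' Initialize a population of agents
#'
#' Places `n_per_region` agents uniformly at random within each region with
#' uniform-integer ages on 1..`max_age`, full energy, normal body temperature
#' and no path knowledge. Adults receive a strategy trait via
#' [assign_initial_traits()]; juveniles stay unset.
#'
#' @param grid A `coop_landscape`.
#' @param config A [coop_config()].
#' @param n_per_region Agents per region (defaults to `config$n_agents`).
#' @return A tibble of agents.
#' @export
init_agents <- function(grid, config, n_per_region = config$n_agents) {
  n <- 2L * n_per_region
  cols_ts <- sample.int(grid$boundary_col, n_per_region, replace = TRUE)
  cols_al <- grid$boundary_col +
    sample.int(grid$width - grid$boundary_col, n_per_region, replace = TRUE)
  agents <- tibble::tibble(
    id = seq_len(n),
    x = as.numeric(c(cols_ts, cols_al)),
    y = as.numeric(sample.int(grid$height, n, replace = TRUE)),
    origin = rep(.regions, each = n_per_region),
    energy = config$max_energy,
    body_temp = config$body_temp_init,
    age = as.numeric(sample.int(config$max_age, n, replace = TRUE)),
    trait = NA_integer_,
    knows_path = FALSE,
    target = NA_integer_,
    dest_x = NA_real_, dest_y = NA_real_,
    low_res_ticks = 0L,
    alive = TRUE,
    death_cause = NA_character_
  )
  assign_initial_traits(agents, config$prob_cooperation, config$adult_age)
}

#' Update body temperatures
#'
#' In cold air (climate temperature below `comfort_temp`) the body cools
#' toward the climate temperature: `T_b <- T_b - (T_b - T_c) * CR`. In milder
#' air thermoregulation succeeds and the body recovers toward normal at
#' `shelter_warming` degrees per tick; in shelter it warms at the same rate
#' regardless of the weather. Warming is capped at the normal body
#' temperature. Agents whose temperature falls below the hypothermia
#' threshold (30 deg C) die.
#'
#' @param agents Agent tibble.
#' @param climate_temp Climate temperature(s), deg C (scalar or per-agent).
#' @param in_shelter Logical (scalar or per-agent): occupying an active
#'   shelter this tick.
#' @param config A [coop_config()]; `cooling_rate` must lie in `[0, 1]`.
#' @return The updated agents; the dead are flagged `alive = FALSE` with
#'   `death_cause = "hypothermia"`.
#' @export
update_body_temperature <- function(agents, climate_temp, in_shelter, config) {
  cr <- config$cooling_rate
  if (cr < 0 || cr > 1) stop("invalid argument: cooling_rate outside [0, 1]")
  live <- agents$alive
  shel <- rep_len(in_shelter, nrow(agents))
  tc <- rep_len(climate_temp, nrow(agents))
  tb <- agents$body_temp
  warmed <- pmin(tb + config$shelter_warming, config$body_temp_init)
  cooled <- tb - (tb - tc) * cr
  agents$body_temp <- ifelse(live,
                             ifelse(shel | tc >= config$comfort_temp,
                                    warmed, cooled),
                             tb)
  if (config$mortality) {
    dead <- live & agents$body_temp < config$hypothermia_threshold
    agents$alive[dead] <- FALSE
    agents$death_cause[dead] <- "hypothermia"
  }
  agents
}

#' Perceived risk of the local situation
#'
#' Risk on a 0-100 scale, decreasing with the local patch resource fraction
#' and with proximity to the nearest active shelter:
#' `risk = 100 * clip(0.5 * d/d_max + 0.5 * (1 - resource_fraction))`,
#' where `d` is the distance to the nearest active shelter and `d_max` the
#' grid diagonal. Standing on an active shelter means risk 0. With no active
#' shelter anywhere the distance term drops and patches alone set the risk.
#'
#' @param agents Agent tibble.
#' @param grid A `coop_landscape`.
#' @param attractors Attractor tibble (see [init_attractors()]).
#' @param config A [coop_config()].
#' @return Numeric vector of risks in `[0, 100]`.
#' @export
perceived_risk <- function(agents, grid, attractors, config) {
  n <- nrow(agents)
  if (n == 0) return(numeric(0))
  px <- round(agents$x); py <- round(agents$y)
  frac <- grid$resource[cbind(py, px)] / pmax(grid$cap[cbind(py, px)], 1e-12)
  act <- attractors[attractors$active, , drop = FALSE]
  if (nrow(act) == 0) {
    risk <- 100 * pmin(pmax(1 - frac, 0), 1)
    return(risk)
  }
  d2 <- outer(agents$x, act$x, "-")^2 + outer(agents$y, act$y, "-")^2
  dmin <- sqrt(matrixStats_rowMins(d2))
  dmax <- sqrt((grid$width - 1)^2 + (grid$height - 1)^2)
  risk <- 100 * pmin(pmax(0.5 * dmin / dmax + 0.5 * (1 - frac), 0), 1)
  risk[dmin < 0.5] <- 0  # standing on an active shelter patch
  risk
}

# Risk multiplier on the base energy cost: mild sensitivity below the
# breakpoint (scaled by human_risk), sharp acceleration above it.
risk_multiplier <- function(risk, config) {
  ifelse(risk > config$risk_threshold,
         1 + (risk - config$risk_threshold) / 20,
         1 + config$human_risk / 100 * risk / 100)
}

#' Update agent energy
#'
#' Outside shelters energy falls by the scenario's base cost times a
#' perceived-risk multiplier (sharply accelerated above the 80% risk
#' breakpoint). Sheltered agents spend nothing here: their upkeep is charged
#' to the shelter store (see [shelter_service()] and the simulator's
#' consumption stage), and the store recharges them, so energy is
#' non-decreasing in shelter while the store lasts. Energy reaching 0 is
#' death.
#'
#' @param agents Agent tibble.
#' @param risk Per-agent risk from [perceived_risk()].
#' @param in_shelter Logical (scalar or per-agent).
#' @param config A [coop_config()].
#' @return The updated agents; the dead are flagged with
#'   `death_cause = "energy"`.
#' @export
update_energy <- function(agents, risk, in_shelter, config) {
  live <- agents$alive
  shel <- rep_len(in_shelter, nrow(agents))
  cost <- ifelse(shel, 0, config$base_energy_cost *
                   risk_multiplier(risk, config))
  e <- ifelse(live, agents$energy - cost, agents$energy)
  agents$energy <- pmax(e, 0)
  if (config$mortality) {
    dead <- live & e <= 0
    agents$alive[dead] <- FALSE
    agents$death_cause[dead] <- "energy"
  }
  agents
}

#' Age one tick and apply age-related mortality
#'
#' Ages advance by 1/12 year per tick. Under the default `"cap"` rule death
#' fires at `max_age` (50 years); under `"hazard"` a geometric per-tick hazard
#' with mean lifespan `max_age` applies instead.
#'
#' @param agents Agent tibble.
#' @param config A [coop_config()].
#' @return The updated agents; deaths flagged with `death_cause = "age"`.
#' @export
age_step <- function(agents, config) {
  live <- agents$alive
  agents$age[live] <- agents$age[live] + 1 / 12
  if (config$mortality) {
    if (config$age_rule == "cap") {
      dead <- live & agents$age >= config$max_age
    } else {
      hazard <- 1 / (config$max_age * 12)
      dead <- live & runif(nrow(agents)) < hazard
    }
    agents$alive[dead] <- FALSE
    agents$death_cause[dead] <- "age"
  }
  agents
}

#' Reproduction check
#'
#' Each living adult (age >= 12) reproduces with probability
#' `reproduction_prob` per tick. Newborns appear at the parent's position
#' with age 0, unset trait, full energy and normal body temperature.
#' Juveniles never reproduce.
#'
#' @param agents Agent tibble.
#' @param config A [coop_config()].
#' @param next_id First id to assign to newborns.
#' @return A tibble of newborns (possibly empty).
#' @export
reproduce <- function(agents, config, next_id = max(agents$id, 0L) + 1L) {
  eligible <- which(agents$alive & agents$age >= config$adult_age)
  if (length(eligible) == 0) return(agents[0, ])
  births <- eligible[runif(length(eligible)) < config$reproduction_prob]
  if (length(births) == 0) return(agents[0, ])
  k <- length(births)
  out <- structure(
    list(
      id = seq.int(as.integer(next_id), length.out = k),
      x = agents$x[births], y = agents$y[births],
      origin = agents$origin[births],
      energy = rep(as.numeric(config$max_energy), k),
      body_temp = rep(as.numeric(config$body_temp_init), k),
      age = rep(0, k),
      trait = rep(NA_integer_, k),
      knows_path = rep(FALSE, k),
      target = rep(NA_integer_, k),
      dest_x = rep(NA_real_, k), dest_y = rep(NA_real_, k),
      low_res_ticks = rep(0L, k),
      alive = rep(TRUE, k),
      death_cause = rep(NA_character_, k)
    ),
    class = "data.frame", row.names = c(NA_integer_, -k)
  )
  if (tibble::is_tibble(agents)) tibble::as_tibble(out) else out
}

#' Learn the path to the nearest shelter
#'
#' Naive agents acquire path knowledge with probability `learning_rate` per
#' tick, selecting the nearest active shelter in their current region as the
#' movement target (ties broken by smallest id). Knowledge referring to a
#' collapsed shelter has to be reset (the simulator does this) before calling.
#'
#' @param agents Agent tibble.
#' @param attractors Attractor tibble.
#' @param grid A `coop_landscape`.
#' @param config A [coop_config()].
#' @return The updated agents.
#' @export
learn_paths <- function(agents, attractors, grid, config) {
  act <- attractors[attractors$active, , drop = FALSE]
  if (nrow(act) == 0) return(agents)
  act <- act[order(act$id), , drop = FALSE]  # smallest-id tie-break
  naive <- which(agents$alive & !agents$knows_path)
  if (length(naive) == 0) return(agents)
  learns <- naive[runif(length(naive)) < config$learning_rate]
  if (length(learns) == 0) return(agents)
  areg <- region_of(grid, act$x)
  for (reg in .regions) {
    cand <- which(areg == reg)
    who <- learns[region_of(grid, agents$x[learns]) == reg]
    if (length(cand) == 0 || length(who) == 0) next
    d2 <- outer(act$x[cand], agents$x[who], "-")^2 +
      outer(act$y[cand], agents$y[who], "-")^2
    best <- cand[max.col(-t(d2), ties.method = "first")]
    agents$knows_path[who] <- TRUE
    agents$target[who] <- act$id[best]
  }
  agents
}

#' Move agents one tick
#'
#' Step length is `speed_km / patch_edge_km` patches. Movement priority:
#' a migration destination, then the known shelter target (greedy
#' straight-line), else a random walk of the same length. Partial steps land
#' on the nearest patch center and positions are clipped to the grid. Agents
#' already within the occupancy radius of their target shelter stay put.
#'
#' @param agents Agent tibble.
#' @param attractors Attractor tibble.
#' @param grid A `coop_landscape`.
#' @param config A [coop_config()].
#' @return The updated agents (migration destinations cleared on arrival).
#' @export
move_agents <- function(agents, attractors, grid, config) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  step <- config$speed_km / grid$patch_edge_km
  if (step <= 0) return(agents)
  live <- agents$alive

  gx <- rep(NA_real_, n); gy <- rep(NA_real_, n)
  has_dest <- live & !is.na(agents$dest_x)
  gx[has_dest] <- agents$dest_x[has_dest]
  gy[has_dest] <- agents$dest_y[has_dest]

  knows <- live & !has_dest & agents$knows_path & !is.na(agents$target)
  if (any(knows)) {
    ai <- match(agents$target[knows], attractors$id)
    ok <- !is.na(ai) & attractors$active[pmax(ai, 1L)]
    kidx <- which(knows)[ok]
    gx[kidx] <- attractors$x[ai[ok]]
    gy[kidx] <- attractors$y[ai[ok]]
  }

  dx <- gx - agents$x; dy <- gy - agents$y
  dist <- sqrt(dx^2 + dy^2)
  goal <- !is.na(gx)
  # within occupancy radius of a shelter target: settle there, do not jitter
  settled <- goal & !has_dest & dist <= config$occupancy_radius
  mv <- which(live & goal & !settled)
  if (length(mv) > 0) {
    f <- pmin(step / pmax(dist[mv], 1e-12), 1)
    agents$x[mv] <- agents$x[mv] + dx[mv] * f
    agents$y[mv] <- agents$y[mv] + dy[mv] * f
  }
  wander <- which(live & !goal)
  if (length(wander) > 0) {
    theta <- runif(length(wander), 0, 2 * pi)
    agents$x[wander] <- agents$x[wander] + step * cos(theta)
    agents$y[wander] <- agents$y[wander] + step * sin(theta)
  }
  moved <- c(mv, wander)
  if (length(moved) > 0) {
    agents$x[moved] <- pmin(pmax(round(agents$x[moved]), 1), grid$width)
    agents$y[moved] <- pmin(pmax(round(agents$y[moved]), 1), grid$height)
  }
  arrived <- has_dest &
    sqrt((agents$dest_x - agents$x)^2 + (agents$dest_y - agents$y)^2) <= 1
  agents$dest_x[arrived] <- NA_real_
  agents$dest_y[arrived] <- NA_real_
  agents
}
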