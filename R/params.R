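#' Per-scenario physiology and environment modifiers
#'
#' The four scenarios differ in the body-temperature cooling rate, the base
#' energy cost per tick, and (for the arid S4) a halved patch resource cap.
#' The extreme cold scenarios S2/S3 cool bodies faster and cost more energy;
#' S4 matches S1 physiologically but halves resource caps.
#'
#' @param scenario One of `"S1"`..`"S4"`.
#' @return A list with `cooling_rate` (fraction per tick), `base_energy_cost`
#'   (energy units per tick) and `cap_multiplier`.
#' @export
scenario_defaults <- function(scenario = c("S1", "S2", "S3", "S4")) {
  scenario <- match.arg(scenario)
  list(
    cooling_rate = c(S1 = 0.02, S2 = 0.05, S3 = 0.05, S4 = 0.02)[[scenario]],
    base_energy_cost = c(S1 = 1, S2 = 2, S3 = 2, S4 = 1)[[scenario]],
    cap_multiplier = c(S1 = 1, S2 = 1, S3 = 1, S4 = 0.5)[[scenario]]
  )
}

#' Simulation configuration
#'
#' Collects every model parameter with its default. Defaults follow the
#' published factor tables where stated (number of agents, speed, learning
#' rate, risk sensitivity, max energy, body temperature, cooperation factors,
#' 1200-tick horizon); parameters the tables leave open (normalization `beta`,
#' failure probability `e`, group benefit `benefit`, shelter rates, regrowth)
#' are documented extrapolations, fixed here and discussed in the methods
#' vignette.
#'
#' @param scenario Climate scenario, `"S1"`..`"S4"`.
#' @param width,height Landscape dimensions in patches.
#' @param n_attractors_per_region Attractor patches (and initial shelters) per
#'   region; the default 3 matches the initial three static attractors.
#' @param boundary_col Region boundary column (default mid-grid).
#' @param patch_edge_km Km per patch edge (`sqrt(0.5)`; each patch is 0.5 km2).
#' @param resource_max Ordinary patch cap (50).
#' @param attractor_cap Attractor patch cap (100).
#' @param regen_rate Resource regeneration per tick. On a patch hosting an
#'   active shelter the regrowth is routed into the shelter store; on a bare
#'   attractor patch it regrows the patch itself. Ordinary patches never
#'   regenerate.
#' @param climate_decay Per-tick climate decay of attractor-patch resources
#'   (0 disables).
#' @param cooling_rate,base_energy_cost,cap_multiplier Per-scenario overrides;
#'   `NULL` takes [scenario_defaults()].
#' @param max_energy Maximum agent energy (100).
#' @param body_temp_init Normal body temperature, deg C (37).
#' @param hypothermia_threshold Death threshold, deg C (30).
#' @param shelter_warming Warming per tick in shelter (or in mild air), deg C
#'   (+1, capped at the normal body temperature).
#' @param comfort_temp Ambient temperature, deg C, above which
#'   thermoregulation succeeds outside shelter and the body recovers instead
#'   of cooling (10).
#' @param shelter_recovery Energy a sheltered agent may draw from the store
#'   per tick (5), debited 1:1.
#' @param risk_threshold Perceived-risk breakpoint above which energy
#'   depletion accelerates (80, on a 0-100 scale).
#' @param human_risk Risk sensitivity below the breakpoint (5).
#' @param adult_age Age (years) at which a strategy trait is adopted and
#'   reproduction becomes possible (12).
#' @param max_age Age cap in years (50); with `age_rule = "cap"` death is
#'   certain at the cap, with `"hazard"` a geometric hazard with mean
#'   lifespan `max_age` applies instead.
#' @param age_rule `"cap"` (default) or `"hazard"`.
#' @param reproduction_prob Per-tick birth probability of an adult (0.10).
#' @param speed_km Movement per tick in km (0.75).
#' @param learning_rate Per-tick probability of learning the path to the
#'   nearest shelter (1).
#' @param prob_cooperation Initial cooperator probability (0.20).
#' @param cost Cost of cooperation C (10).
#' @param punishment Punishment rho applied to defectors (7).
#' @param prob_nocoop Spontaneous defection probability per tick (0.001).
#' @param alpha Strength of conformist transmission in `[0, 1]` (0.20).
#' @param beta Normalization of the payoff term (0.05): sized so the
#'   payoff-biased and conformist channels are comparable at the default
#'   payoff scales.
#' @param fail_prob Probability `e` of failing in cooperation (0.1).
#' @param benefit Group benefit B (20).
#' @param p1 Punisher frequency; `NULL` (default) ties it to the current
#'   cooperator frequency each tick.
#' @param radius_strategy Neighborhood radius, in patches, for social
#'   pressure, trait adoption and shelter founding (3).
#' @param consumption_coop,consumption_defect,consumption_juvenile Resource
#'   units drawn per tick by cooperators (1), defectors (2) and juveniles (1).
#' @param altai_multiplier Consumption multiplier in the Altai (1.25), where
#'   resources are more limited.
#' @param occupancy_radius Shelter occupancy radius in patches (1).
#' @param min_cooperators,min_companions Founding requires at least this many
#'   cooperators and total neighbors near the initiating cooperator (1 / 2).
#' @param min_spacing_km Minimum distance between active shelters (5 km).
#' @param initial_store Store of a newly founded shelter (500 energy units).
#' @param n_agents Initial agents per region (10).
#' @param ticks Simulation horizon in months (1200 = 100 years).
#' @param migration_threshold Patch resource fraction below which a patch
#'   counts as depleted (0.20).
#' @param migration_wait Consecutive depleted ticks before migrating (6).
#' @param start_season Season at tick 0 (`"winter"`).
#' @param allow_cross_region Whether migrants may cross the region boundary.
#' @param max_population Demographic ceiling: births are suppressed while the
#'   total population is at or above it (400).
#' @param mortality Master switch for all death channels (energy,
#'   hypothermia, age); used by invariant checks.
#' @param ... Ignored; present so configs can be built programmatically.
#' @return A `coop_config` list.
#' @export
#' @examples
#' cfg <- coop_config(scenario = "S2", width = 128, height = 64)
#' cfg$cooling_rate
coop_config <- function(scenario = "S1",
                        width = 534L, height = 328L,
                        n_attractors_per_region = 3L,
                        boundary_col = width %/% 2L,
                        patch_edge_km = sqrt(0.5),
                        resource_max = 50,
                        attractor_cap = 100,
                        regen_rate = 40,
                        climate_decay = 0,
                        cooling_rate = NULL,
                        base_energy_cost = NULL,
                        cap_multiplier = NULL,
                        max_energy = 100,
                        body_temp_init = 37,
                        hypothermia_threshold = 30,
                        shelter_warming = 1,
                        comfort_temp = 10,
                        shelter_recovery = 5,
                        risk_threshold = 80,
                        human_risk = 5,
                        adult_age = 12,
                        max_age = 50,
                        age_rule = c("cap", "hazard"),
                        reproduction_prob = 0.10,
                        speed_km = 0.75,
                        learning_rate = 1,
                        prob_cooperation = 0.20,
                        cost = 10,
                        punishment = 7,
                        prob_nocoop = 0.001,
                        alpha = 0.20,
                        beta = 0.05,
                        fail_prob = 0.1,
                        benefit = 20,
                        p1 = NULL,
                        radius_strategy = 3,
                        consumption_coop = 1,
                        consumption_defect = 2,
                        consumption_juvenile = 1,
                        altai_multiplier = 1.25,
                        occupancy_radius = 1,
                        min_cooperators = 1,
                        min_companions = 2,
                        min_spacing_km = 5,
                        initial_store = 500,
                        n_agents = 10L,
                        ticks = 1200L,
                        migration_threshold = 0.20,
                        migration_wait = 6L,
                        start_season = "winter",
                        allow_cross_region = TRUE,
                        max_population = 400L,
                        mortality = TRUE,
                        ...) {
  scenario <- match.arg(scenario, .scenarios)
  age_rule <- match.arg(age_rule)
  scen <- scenario_defaults(scenario)
  cfg <- list(
    scenario = scenario,
    width = as.integer(width), height = as.integer(height),
    n_attractors_per_region = as.integer(n_attractors_per_region),
    boundary_col = as.integer(boundary_col),
    patch_edge_km = patch_edge_km,
    resource_max = resource_max, attractor_cap = attractor_cap,
    regen_rate = regen_rate, climate_decay = climate_decay,
    cooling_rate = cooling_rate %||% scen$cooling_rate,
    base_energy_cost = base_energy_cost %||% scen$base_energy_cost,
    cap_multiplier = cap_multiplier %||% scen$cap_multiplier,
    max_energy = max_energy, body_temp_init = body_temp_init,
    hypothermia_threshold = hypothermia_threshold,
    shelter_warming = shelter_warming, comfort_temp = comfort_temp,
    shelter_recovery = shelter_recovery,
    risk_threshold = risk_threshold, human_risk = human_risk,
    adult_age = adult_age, max_age = max_age, age_rule = age_rule,
    reproduction_prob = reproduction_prob,
    speed_km = speed_km, learning_rate = learning_rate,
    prob_cooperation = prob_cooperation, cost = cost,
    punishment = punishment, prob_nocoop = prob_nocoop,
    alpha = alpha, beta = beta, fail_prob = fail_prob, benefit = benefit,
    p1 = p1, radius_strategy = radius_strategy,
    consumption_coop = consumption_coop,
    consumption_defect = consumption_defect,
    consumption_juvenile = consumption_juvenile,
    altai_multiplier = altai_multiplier,
    occupancy_radius = occupancy_radius,
    min_cooperators = min_cooperators, min_companions = min_companions,
    min_spacing_km = min_spacing_km, initial_store = initial_store,
    n_agents = as.integer(n_agents), ticks = as.integer(ticks),
    migration_threshold = migration_threshold,
    migration_wait = as.integer(migration_wait),
    start_season = match.arg(start_season, .seasons),
    allow_cross_region = isTRUE(allow_cross_region),
    max_population = as.integer(max_population),
    mortality = isTRUE(mortality)
  )
  class(cfg) <- "coop_config"
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' Checks every module's parameter invariants; called by [coop_config()] and
#' again at the start of a run.
#'
#' @param config A `coop_config`.
#' @return The config, invisibly; a validation error otherwise.
#' @export
validate_config <- function(config) {
  with(config, {
    probs <- c(prob_cooperation, prob_nocoop, alpha, fail_prob,
               learning_rate, reproduction_prob, migration_threshold)
    if (any(probs < 0 | probs > 1)) {
      stop("probabilities and alpha/e must lie in [0, 1]")
    }
    if (cooling_rate < 0 || cooling_rate > 1) {
      stop("invalid argument: cooling_rate must lie in [0, 1]")
    }
    if (!is.null(p1) && (p1 < 0 || p1 > 1)) stop("p1 must lie in [0, 1]")
    if (any(c(cost, punishment, benefit, beta, regen_rate, climate_decay,
              base_energy_cost, shelter_recovery, initial_store,
              speed_km) < 0)) {
      stop("rates, costs and stores must be >= 0")
    }
    if (hypothermia_threshold >= body_temp_init) {
      stop("hypothermia_threshold must be below the normal body temperature")
    }
    if (width < 2 || height < 2) stop("grid must be at least 2 x 2")
    if (ticks < 0 || n_agents < 0) stop("ticks and n_agents must be >= 0")
  })
  invisible(config)
}

#' @export
print.coop_config <- function(x, ...) {
  cat("<coop_config> scenario", x$scenario, "|",
      x$width, "x", x$height, "patches |", x$n_agents,
      "agents/region |", x$ticks, "ticks\n")
  cat("  cooperation: p0 =", x$prob_cooperation, " alpha =", x$alpha,
      " cost =", x$cost, " punishment =", x$punishment, "\n")
  cat("  physiology: CR =", x$cooling_rate, " base cost =",
      x$base_energy_cost, "/tick  cap x", x$cap_multiplier, "\n")
  invisible(x)
}
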