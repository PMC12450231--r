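# Attractors ("shelters") are resource-rich places that grant energy and
# warmth. State: one row per attractor ever founded, with an activity flag
# and founding/collapse ticks so activity windows can be reconstructed.

attractor_row <- function(id, x, y, region, store, tick) {
  k <- length(id)
  structure(
    list(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
         region = as.character(region), store = rep_len(as.numeric(store), k),
         active = rep(TRUE, k), founded_tick = rep_len(as.integer(tick), k),
         collapsed_tick = rep(NA_integer_, k)),
    class = "data.frame", row.names = c(NA_integer_, -k)
  )
}

#' Initial shelters on the landscape's attractor patches
#'
#' Creates one active shelter per attractor patch (by default three per
#' region), each with the configured initial store.
#'
#' @param grid A `coop_landscape`.
#' @param config A [coop_config()].
#' @return An attractor tibble with columns `id`, `x`, `y`, `region`,
#'   `store`, `active`, `founded_tick`, `collapsed_tick`.
#' @export
init_attractors <- function(grid, config) {
  idx <- which(grid$attractor, arr.ind = TRUE)
  if (nrow(idx) == 0) return(attractor_row(integer(0), numeric(0),
                                           numeric(0), character(0),
                                           numeric(0), integer(0)))
  ord <- order(idx[, "col"], idx[, "row"])
  idx <- idx[ord, , drop = FALSE]
  attractor_row(seq_len(nrow(idx)), idx[, "col"], idx[, "row"],
                region_of(grid, idx[, "col"]), config$initial_store, 0L)
}

# Pairwise-spacing check of a candidate position against active shelters.
spacing_ok <- function(x, y, attractors, config, grid) {
  act <- attractors[attractors$active, , drop = FALSE]
  if (nrow(act) == 0) return(TRUE)
  d_km <- sqrt((act$x - x)^2 + (act$y - y)^2) * grid$patch_edge_km
  all(d_km >= config$min_spacing_km)
}

#' Can a shelter be founded here?
#'
#' Founding requires all three conditions: (a) at least `min_spacing_km`
#' (5 km) from every active shelter, (b) the hosting patch retains at least
#' 50% of its resource cap, and (c) enough company near the initiating
#' cooperator: at least `min_cooperators` cooperators and `min_companions`
#' total neighbors (the initiator itself is not counted).
#'
#' @param x,y Candidate patch position.
#' @param grid A `coop_landscape`.
#' @param attractors Attractor tibble.
#' @param n_cooperators Cooperators among the nearby agents.
#' @param n_companions Total nearby agents.
#' @param config A [coop_config()].
#' @return `TRUE` or `FALSE`.
#' @export
can_found_attractor <- function(x, y, grid, attractors, n_cooperators,
                                n_companions, config) {
  px <- round(x); py <- round(y)
  if (px < 1 || px > grid$width || py < 1 || py > grid$height) return(FALSE)
  spacing_ok(px, py, attractors, config, grid) &&
    grid$resource[py, px] >= 0.5 * grid$cap[py, px] &&
    n_cooperators >= config$min_cooperators &&
    n_companions >= config$min_companions
}

#' Found a new shelter
#'
#' Appends an active shelter with the configured initial store. The spacing
#' invariant is re-checked; founding at a violating position is an error
#' (callers must check [can_found_attractor()] first).
#'
#' @param attractors Attractor tibble.
#' @param x,y Position (patch).
#' @param grid A `coop_landscape`.
#' @param tick Founding tick.
#' @param config A [coop_config()].
#' @return The attractor tibble with one more row.
#' @export
found_attractor <- function(attractors, x, y, grid, tick, config) {
  if (!spacing_ok(x, y, attractors, config, grid)) {
    stop("invariant violation: founding a shelter within ",
         config$min_spacing_km, " km of an active shelter")
  }
  next_id <- if (nrow(attractors) == 0) 1L else max(attractors$id) + 1L
  out <- rbind(
    as.data.frame(attractors),
    attractor_row(next_id, x, y, region_of(grid, x), config$initial_store,
                  tick)
  )
  if (tibble::is_tibble(attractors)) tibble::as_tibble(out) else out
}

#' Shelter services for occupants
#'
#' Each living agent within the occupancy radius of an active shelter is
#' warmed (+1 deg C per tick, capped at the normal body temperature) and may
#' draw energy from the store: the request is the recovery rate capped by the
#' distance to full energy, granted pro rata when the store cannot serve
#' everyone. The store is debited 1:1; cooperators and defectors are served
#' identically.
#'
#' @param agents Agent tibble.
#' @param attractors Attractor tibble.
#' @param config A [coop_config()].
#' @param warm Also apply the warming service (the simulator applies warming
#'   in its climate stage instead and passes `FALSE`).
#' @param occ Optional precomputed occupancy vector (from the internal
#'   assignment of agents to their nearest active shelter within the
#'   occupancy radius); computed when `NULL`.
#' @return A list with updated `agents`, `attractors`, and `occupant`
#'   (per-agent id of the serving shelter, `NA` if unsheltered).
#' @export
shelter_service <- function(agents, attractors, config, warm = TRUE,
                            occ = NULL) {
  if (is.null(occ)) occ <- occupancy(agents, attractors, config)
  served <- which(!is.na(occ) & agents$alive)
  if (length(served) > 0) {
    if (warm) {
      agents$body_temp[served] <-
        pmin(agents$body_temp[served] + config$shelter_warming,
             config$body_temp_init)
    }
    request <- pmin(config$shelter_recovery,
                    config$max_energy - agents$energy[served])
    grant <- numeric(length(served))
    for (aid in unique(occ[served])) {
      rows <- which(occ[served] == aid)
      ai <- match(aid, attractors$id)
      tot <- sum(request[rows])
      if (tot <= 0) next
      share <- min(1, attractors$store[ai] / tot)
      grant[rows] <- request[rows] * share
      attractors$store[ai] <- attractors$store[ai] - sum(grant[rows])
    }
    agents$energy[served] <- pmin(agents$energy[served] + grant,
                                  config$max_energy)
  }
  list(agents = agents, attractors = attractors, occupant = occ)
}

# Per-agent id of the nearest active shelter within the occupancy radius
# (NA when unsheltered); ties go to the smallest shelter id.
occupancy <- function(agents, attractors, config) {
  n <- nrow(agents)
  occ <- rep(NA_integer_, n)
  keep <- which(attractors$active)
  if (n == 0 || length(keep) == 0) return(occ)
  keep <- keep[order(attractors$id[keep])]
  ax <- attractors$x[keep]; ay <- attractors$y[keep]
  d2 <- outer(agents$x, ax, "-")^2 + outer(agents$y, ay, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(n), nearest)]
  inside <- dmin <= config$occupancy_radius^2
  occ[inside] <- attractors$id[keep][nearest[inside]]
  occ
}

#' Deactivate exhausted shelters
#'
#' A shelter whose store has reached zero collapses: it becomes inactive and
#' invisible to learning, risk and shelter services. A strictly positive
#' store, however small, keeps it active.
#'
#' @param attractors Attractor tibble.
#' @param tick Tick to record as the collapse tick.
#' @return The updated attractor tibble.
#' @export
deactivate_empty <- function(attractors, tick = NA_integer_) {
  gone <- attractors$active & attractors$store <= 1e-9
  attractors$store[gone] <- 0
  attractors$active[gone] <- FALSE
  attractors$collapsed_tick[gone] <- as.integer(tick)
  attractors
}
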