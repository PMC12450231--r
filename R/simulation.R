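# The tick scheduler. One tick is one month. Stage order within a tick:
#   1 climate update and body-temperature physiology (hypothermia deaths)
#   2 path learning (knowledge of collapsed shelters is reset first)
#   3 cooperation: per-region payoff difference -> delta_p -> strategy update
#   4 consumption and energy: patch depletion, shelter services, risk-scaled
#     energy costs (energy deaths)
#   5 settlement: founding attempts, collapse of empty shelters, regrowth
#   6 migration check and movement
#   7 aging (age deaths), trait adoption at adulthood, reproduction
#   8 bookkeeping into the run series
# Dead agents are removed at the stage where death fires.

.series_metrics <- c("population", "cooperators", "defectors", "juveniles",
                     "attractors_active", "mean_energy", "mean_body_temp",
                     "p_o", "delta_p", "payoff_c", "payoff_d")

#' Initialize a simulation state
#'
#' Builds the landscape (unless one is supplied), the initial shelters (one
#' per attractor patch) and the initial population (equal numbers per region,
#' ages uniform on 1..50, adult traits Bernoulli with the configured
#' cooperation probability). Randomness is drawn from the current RNG stream;
#' seed via [run_simulation()] or `set.seed()`.
#'
#' @param config A [coop_config()].
#' @param grid Optional pre-built `coop_landscape`.
#' @return A `coop_state` environment.
#' @export
sim_init <- function(config, grid = NULL) {
  validate_config(config)
  if (is.null(grid)) {
    grid <- synthetic_landscape(
      width = config$width, height = config$height,
      n_attractors_per_region = config$n_attractors_per_region,
      boundary_col = config$boundary_col,
      patch_edge_km = config$patch_edge_km,
      resource_max = config$resource_max,
      attractor_cap = config$attractor_cap,
      cap_multiplier = config$cap_multiplier,
      min_spacing_km = config$min_spacing_km
    )
  }
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$grid <- grid
  state$schedule <- scenario_schedule(config$scenario)
  state$attractors <- as.data.frame(init_attractors(grid, config))
  state$agents <- as.data.frame(init_agents(grid, config))
  state$next_id <- if (nrow(state$agents)) max(state$agents$id) + 1L else 1L
  state$tick <- 0L
  nrow_series <- config$ticks + 1L
  state$series <- array(
    NA_real_, dim = c(nrow_series, 2L, length(.series_metrics)),
    dimnames = list(NULL, .regions, .series_metrics)
  )
  state$events <- vector("list", 256L)
  state$n_events <- 0L
  state$extinct <- FALSE
  state$extinction_tick <- NA_integer_
  state$dp_last <- c(TianShan = NA_real_, Altai = NA_real_)
  state$payoff_last <- matrix(NA_real_, 2, 2,
                              dimnames = list(.regions, c("b_c", "b_d")))
  record_tick(state)
  class(state) <- c("coop_state", "environment")
  state
}

log_event <- function(state, event, id, region, cause = NA_character_) {
  k <- length(id)
  if (k == 0) return(invisible())
  state$n_events <- state$n_events + 1L
  if (state$n_events > length(state$events)) {
    state$events <- c(state$events, vector("list", length(state$events)))
  }
  state$events[[state$n_events]] <-
    list(tick = rep(state$tick, k), event = rep(event, k), id = id,
         region = region, cause = rep_len(cause, k))
  invisible()
}

# remove the newly dead, logging a death event with its cause
reap <- function(state) {
  dead <- which(!state$agents$alive)
  if (length(dead) == 0) return(invisible())
  ag <- state$agents
  log_event(state, "death", ag$id[dead],
            region_of(state$grid, ag$x[dead]), ag$death_cause[dead])
  state$agents <- ag[-dead, , drop = FALSE]
  invisible()
}

record_tick <- function(state) {
  ag <- state$agents
  row <- state$tick + 1L
  reg <- region_of(state$grid, ag$x)
  att_reg <- state$attractors$region[state$attractors$active]
  for (r in .regions) {
    sel <- reg == r
    adult <- sel & !is.na(ag$trait)
    nc <- sum(ag$trait[adult] == 1L)
    nd <- sum(ag$trait[adult] == 0L)
    state$series[row, r, ] <- c(
      population = sum(sel),
      cooperators = nc,
      defectors = nd,
      juveniles = sum(sel & is.na(ag$trait)),
      attractors_active = sum(att_reg == r),
      mean_energy = if (any(sel)) mean(ag$energy[sel]) else NA_real_,
      mean_body_temp = if (any(sel)) mean(ag$body_temp[sel]) else NA_real_,
      p_o = if (nc + nd > 0) nc / (nc + nd) else NA_real_,
      delta_p = state$dp_last[[r]],
      payoff_c = state$payoff_last[r, "b_c"],
      payoff_d = state$payoff_last[r, "b_d"]
    )
  }
  invisible()
}

#' Advance the simulation by one tick
#'
#' Executes the eight within-tick stages in order (see the package vignette
#' for the schedule). Exposed mainly for tests and inspection; normal use
#' goes through [run_simulation()].
#'
#' @param state A `coop_state` from [sim_init()].
#' @return The state, invisibly (modified in place).
#' @export
sim_step <- function(state) {
  cfg <- state$config
  grid <- state$grid
  ag <- state$agents

  # --- stage 1: climate forcing and body temperature -----------------------
  occ <- NULL
  if (nrow(ag) > 0) {
    reg <- region_of(grid, ag$x)
    tc <- temperature_at(state$schedule, reg, state$tick, cfg$start_season)
    occ <- occupancy(ag, state$attractors, cfg)
    ag <- update_body_temperature(ag, tc, !is.na(occ), cfg)
    if (any(!ag$alive)) {
      state$agents <- ag
      reap(state)
      ag <- state$agents
      occ <- NULL  # rows changed
    }
  }

  # --- stage 2: learning ---------------------------------------------------
  if (nrow(ag) > 0) {
    active_ids <- state$attractors$id[state$attractors$active]
    stale <- ag$knows_path & !(ag$target %in% active_ids)
    ag$knows_path[stale] <- FALSE
    ag$target[stale] <- NA_integer_
    ag <- learn_paths(ag, state$attractors, grid, cfg)
  }

  # --- stage 3: cooperation ------------------------------------------------
  state$dp_last[] <- NA_real_
  state$payoff_last[] <- NA_real_
  if (nrow(ag) > 0) {
    reg <- region_of(grid, ag$x)
    for (r in .regions) {
      idx <- which(reg == r)
      adult <- idx[!is.na(ag$trait[idx]) & ag$alive[idx]]
      n <- length(adult)
      if (n == 0) next
      p_o <- mean(ag$trait[adult] == 1L)
      p1 <- cfg$p1 %||% p_o
      e <- cfg$fail_prob
      db <- (1 - e) * (n * p1 * (1 - e) * cfg$punishment - cfg$cost)
      b_d <- (1 - e) * (p_o * cfg$benefit - n * p1 * cfg$punishment)
      b_c <- (1 - e) * (p_o * cfg$benefit * (1 - e) - cfg$cost +
                          e * (p_o * cfg$benefit - n * p1 * cfg$punishment))
      dp <- p_o * (1 - p_o) *
        ((1 - cfg$alpha) * cfg$beta * db + cfg$alpha * (2 * p_o - 1))
      dp <- min(max(dp, -p_o), 1 - p_o)  # clamp p_o + dp into [0, 1]
      # stage 1 carries the payoff-biased channel; the conformist channel is
      # realized spatially by the kernel's stage 2 (no double counting)
      dp_payoff <- p_o * (1 - p_o) * (1 - cfg$alpha) * cfg$beta * db
      dp_payoff <- min(max(dp_payoff, -p_o), 1 - p_o)
      ag$trait[adult] <- strategy_kernel(ag$trait[adult], ag$x[adult],
                                         ag$y[adult], dp_payoff, cfg)
      state$dp_last[[r]] <- dp
      state$payoff_last[r, ] <- c(b_c, b_d)
    }
  }

  # --- stage 4: consumption, shelter services, energy ----------------------
  if (nrow(ag) > 0) {
    # positions and the shelter set are unchanged since stage 1, so the
    # occupancy computed there (if no one died) is still valid
    if (is.null(occ)) occ <- occupancy(ag, state$attractors, cfg)
    sheltered <- !is.na(occ)
    reg <- region_of(grid, ag$x)
    draw <- ifelse(is.na(ag$trait), cfg$consumption_juvenile,
                   ifelse(ag$trait == 1L, cfg$consumption_coop,
                          cfg$consumption_defect))
    draw <- draw * ifelse(reg == "Altai", cfg$altai_multiplier, 1)
    out <- which(!sheltered & ag$alive)
    if (length(out) > 0) {
      grid <- consume_resources(grid, as.integer(round(ag$x[out])),
                                as.integer(round(ag$y[out])), draw[out])
    }
    # occupants are provisioned by the store: their upkeep and their
    # resource draw are debited from it (defectors drain it faster)
    svc <- shelter_service(ag, state$attractors, cfg, warm = FALSE, occ = occ)
    ag <- svc$agents
    atts <- svc$attractors
    ins <- which(sheltered & ag$alive)
    if (length(ins) > 0) {
      debit <- rowsum(draw[ins] + cfg$base_energy_cost, occ[ins])
      ai <- match(as.integer(rownames(debit)), atts$id)
      atts$store[ai] <- pmax(atts$store[ai] - debit[, 1], 0)
    }
    state$attractors <- atts
    risk <- perceived_risk(ag, grid, state$attractors, cfg)
    ag <- update_energy(ag, risk, sheltered, cfg)
    state$grid <- grid
    state$agents <- ag
    reap(state)
    ag <- state$agents
  }

  # --- stage 5: settlement -------------------------------------------------
  atts <- state$attractors
  if (nrow(ag) > 0) {
    founders <- which(ag$alive & !is.na(ag$trait) & ag$trait == 1L)
    if (length(founders) > 0) {
      founders <- founders[order(ag$id[founders])]
      px <- round(ag$x); py <- round(ag$y)
      frac_ok <- grid$resource[cbind(py[founders], px[founders])] >=
        0.5 * grid$cap[cbind(py[founders], px[founders])]
      founders <- founders[frac_ok]
      # vectorized spacing prefilter against the current active set (the
      # sequential loop re-checks against shelters founded this tick)
      if (length(founders) > 0) {
        act0 <- atts[atts$active, , drop = FALSE]
        if (nrow(act0) > 0) {
          d2 <- outer(px[founders], act0$x, "-")^2 +
            outer(py[founders], act0$y, "-")^2
          min_d2 <- (cfg$min_spacing_km / grid$patch_edge_km)^2
          founders <- founders[matrixStats_rowMins(d2) >= min_d2]
        }
      }
      for (f in founders) {
        nb <- which(ag$alive & ag$id != ag$id[f] &
                      (ag$x - ag$x[f])^2 + (ag$y - ag$y[f])^2 <=
                      cfg$radius_strategy^2)
        n_coop <- sum(ag$trait[nb] == 1L, na.rm = TRUE)
        if (can_found_attractor(px[f], py[f], grid, atts, n_coop,
                                length(nb), cfg)) {
          atts <- found_attractor(atts, px[f], py[f], grid, state$tick, cfg)
          log_event(state, "founded", max(atts$id),
                    atts$region[nrow(atts)])
        }
      }
      atts <- as.data.frame(atts)
    }
  }
  was_active <- atts$active
  atts <- deactivate_empty(atts, state$tick)
  collapsed <- was_active & !atts$active
  if (any(collapsed)) {
    log_event(state, "collapsed", atts$id[collapsed], atts$region[collapsed])
  }
  # regrowth: active shelters absorb their patch's regrowth into the store;
  # bare attractor patches regrow (minus any climate decay); ordinary
  # patches never regenerate
  act <- atts$active
  if (any(act)) atts$store[act] <- atts$store[act] + cfg$regen_rate
  hosts <- matrix(FALSE, grid$height, grid$width)
  if (any(act)) hosts[cbind(round(atts$y[act]), round(atts$x[act]))] <- TRUE
  bare <- grid$attractor & !hosts
  grid$resource[bare] <- pmax(0, pmin(
    grid$resource[bare] + cfg$regen_rate - cfg$climate_decay,
    grid$cap[bare]
  ))
  state$attractors <- atts
  state$grid <- grid

  # --- stage 6: migration and movement -------------------------------------
  if (nrow(ag) > 0) {
    occ <- occupancy(ag, atts, cfg)
    px <- as.integer(round(ag$x)); py <- as.integer(round(ag$y))
    frac <- grid$resource[cbind(py, px)] / pmax(grid$cap[cbind(py, px)], 1e-12)
    depleted <- ag$alive & is.na(occ) & frac < cfg$migration_threshold
    ag$low_res_ticks <- ifelse(depleted, ag$low_res_ticks + 1L, 0L)
    need <- which(ag$alive & is.na(ag$dest_x) &
                    ag$low_res_ticks >= cfg$migration_wait)
    if (length(need) > 0) {
      dest <- migration_destinations(ag, need, grid, atts, cfg)
      ok <- !is.na(dest$x)
      ag$dest_x[need[ok]] <- dest$x[ok]
      ag$dest_y[need[ok]] <- dest$y[ok]
      ag$low_res_ticks[need[ok]] <- 0L
    }
    ag <- move_agents(ag, atts, grid, cfg)
  }

  # --- stage 7: demography -------------------------------------------------
  if (nrow(ag) > 0) {
    ag <- age_step(ag, cfg)
    state$agents <- ag
    reap(state)
    ag <- state$agents
  }
  if (nrow(ag) > 0) {
    ag <- adopt_traits(ag, grid, cfg)
    if (nrow(ag) < cfg$max_population && cfg$reproduction_prob > 0) {
      babies <- reproduce(ag, cfg, state$next_id)
      if (nrow(babies) > 0) {
        state$next_id <- state$next_id + nrow(babies)
        ag <- rbind(ag, as.data.frame(babies))
        log_event(state, "birth", babies$id, region_of(grid, babies$x))
      }
    }
  }
  state$agents <- ag

  # --- stage 8: bookkeeping ------------------------------------------------
  state$tick <- state$tick + 1L
  record_tick(state)
  if (nrow(ag) == 0 && !state$extinct) {
    state$extinct <- TRUE
    state$extinction_tick <- state$tick
  }
  invisible(state)
}

# nearest viable patch (resource fraction above the migration threshold) for
# each migrant; patches near an active shelter are preferred. Migrants on the
# same patch share a destination. NA when no viable patch exists.
migration_destinations <- function(ag, need, grid, atts, cfg) {
  out <- list(x = rep(NA_real_, length(need)), y = rep(NA_real_, length(need)))
  viable <- grid$resource >= cfg$migration_threshold * grid$cap
  if (!any(viable)) return(out)
  act <- atts[atts$active, , drop = FALSE]
  # preferred destinations: viable patches in the vicinity of a shelter
  pref <- matrix(FALSE, grid$height, grid$width)
  r <- ceiling(cfg$radius_strategy)
  for (i in seq_len(nrow(act))) {
    xs <- max(1, act$x[i] - r):min(grid$width, act$x[i] + r)
    ys <- max(1, act$y[i] - r):min(grid$height, act$y[i] + r)
    pref[ys, xs] <- TRUE
  }
  pref <- pref & viable
  px <- round(ag$x[need]); py <- round(ag$y[need])
  preg <- region_of(grid, px)
  key <- paste(px, py, preg)
  for (k in unique(key)) {
    rows <- which(key == k)
    x0 <- px[rows[1]]; y0 <- py[rows[1]]
    reg <- if (cfg$allow_cross_region) NULL else preg[rows[1]]
    best <- nearest_cell(pref, x0, y0, grid, reg)
    if (is.null(best)) best <- nearest_cell(viable, x0, y0, grid, reg)
    if (is.null(best)) next
    out$x[rows] <- best[1]
    out$y[rows] <- best[2]
  }
  out
}

# nearest TRUE cell of a mask to (x0, y0) by expanding window search;
# optionally restricted to one region. NULL when the mask is empty.
nearest_cell <- function(mask, x0, y0, grid, region = NULL) {
  w <- grid$width; h <- grid$height
  r <- 4L
  repeat {
    xs <- max(1, x0 - r):min(w, x0 + r)
    if (!is.null(region)) {
      xs <- if (region == "TianShan") xs[xs <= grid$boundary_col]
            else xs[xs > grid$boundary_col]
    }
    ys <- max(1, y0 - r):min(h, y0 + r)
    if (length(xs) > 0) {
      sub <- mask[ys, xs, drop = FALSE]
      hit <- which(sub, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        cx <- xs[hit[, "col"]]; cy <- ys[hit[, "row"]]
        d2 <- (cx - x0)^2 + (cy - y0)^2
        best <- which.min(d2)
        # accept only if within the guaranteed-complete search radius,
        # otherwise widen once more (a nearer cell could sit outside the box)
        if (sqrt(d2[best]) <= r || r >= max(w, h)) {
          return(c(cx[best], cy[best]))
        }
      }
    }
    if (r >= max(w, h)) return(NULL)
    r <- min(r * 4L, max(w, h))
  }
}

matrixStats_rowMins <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Run a full simulation
#'
#' Initializes the landscape, shelters and agents, then advances the
#' scheduler for the configured number of ticks (or until extinction; the
#' series is then padded with zero populations to keep it rectangular).
#'
#' @param config A [coop_config()].
#' @param seed Optional integer seed; identical (config, seed) pairs give
#'   bit-identical results.
#' @param grid Optional pre-built `coop_landscape`.
#' @return A `coop_run` with elements `series` (tidy per-tick, per-region
#'   tibble), `events` (birth/death/founding log), `attractors` (every
#'   shelter ever founded with its activity window), `config`, `seed`,
#'   `extinct` and `extinction_tick`. See [tidy.coop_run()],
#'   [glance.coop_run()] and [autoplot.coop_run()].
#' @export
#' @examples
#' cfg <- coop_config(width = 40, height = 20, ticks = 24)
#' run <- run_simulation(cfg, seed = 1)
#' glance(run)
run_simulation <- function(config = coop_config(), seed = NULL, grid = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  state <- sim_init(config, grid = grid)
  while (state$tick < config$ticks) {
    sim_step(state)
    if (state$extinct) break
  }
  # pad after extinction: zero counts, NA means
  if (state$extinct && state$tick < config$ticks) {
    rows <- seq.int(state$tick + 2L, config$ticks + 1L)
    zero <- c("population", "cooperators", "defectors", "juveniles")
    state$series[rows, , zero] <- 0
    att_reg <- state$attractors$region[state$attractors$active]
    for (r in .regions) {
      state$series[rows, r, "attractors_active"] <- sum(att_reg == r)
    }
    state$tick <- config$ticks
  }
  as_coop_run(state, seed)
}

as_coop_run <- function(state, seed) {
  s <- state$series
  long <- tidyr::pivot_longer(
    dplyr::bind_rows(lapply(.regions, function(r) {
      m <- matrix(s[, r, ], ncol = dim(s)[3],
                  dimnames = list(NULL, .series_metrics))
      df <- tibble::as_tibble(m)
      df$tick <- seq_len(nrow(df)) - 1L
      df$region <- r
      df
    })),
    cols = dplyr::all_of(.series_metrics),
    names_to = "metric", values_to = "value"
  )
  series <- tidyr::pivot_wider(long, names_from = "metric",
                               values_from = "value")
  events <- if (state$n_events > 0) {
    evs <- state$events[seq_len(state$n_events)]
    tibble::tibble(
      tick = unlist(lapply(evs, `[[`, "tick")),
      event = unlist(lapply(evs, `[[`, "event")),
      id = unlist(lapply(evs, `[[`, "id")),
      region = unlist(lapply(evs, `[[`, "region")),
      cause = unlist(lapply(evs, `[[`, "cause"))
    )
  } else {
    tibble::tibble(tick = integer(0), event = character(0), id = integer(0),
                   region = character(0), cause = character(0))
  }
  structure(
    list(series = series, events = events,
         attractors = tibble::as_tibble(state$attractors),
         agents = tibble::as_tibble(state$agents),
         config = state$config, seed = seed,
         ticks_run = state$tick, extinct = state$extinct,
         extinction_tick = state$extinction_tick),
    class = "coop_run"
  )
}

#' @export
print.coop_run <- function(x, ...) {
  fin <- x$series[x$series$tick == max(x$series$tick), ]
  cat("<coop_run>", x$config$scenario, "|", x$ticks_run, "ticks |",
      if (x$extinct) paste0("EXTINCT at tick ", x$extinction_tick)
      else "survived", "\n")
  cat("final population:",
      paste(fin$region, fin$population, collapse = ", "), "\n")
  invisible(x)
}
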