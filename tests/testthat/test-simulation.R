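test_that("configs validate their invariants", {
  expect_s3_class(small_config(), "coop_config")
  expect_error(small_config(prob_cooperation = 1.2), "\\[0, 1\\]")
  expect_error(small_config(cost = -1), ">= 0")
  expect_error(small_config(hypothermia_threshold = 40), "below")
  expect_error(small_config(cooling_rate = 2), "\\[0, 1\\]")
  # scenario defaults flow into the config
  expect_equal(coop_config(scenario = "S2", width = 10, height = 10,
                           n_attractors_per_region = 0)$cooling_rate, 0.05)
  expect_equal(coop_config(scenario = "S4", width = 10, height = 10,
                           n_attractors_per_region = 0)$cap_multiplier, 0.5)
})

test_that("an empty population ticks through with all-zero series", {
  cfg <- small_config(n_agents = 0, ticks = 5)
  run <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(run$series), 2 * 6)
  expect_true(all(run$series$population == 0))
  expect_true(run$extinct)
})

test_that("a zero-tick run returns only the initial snapshot", {
  cfg <- small_config(ticks = 0)
  run <- run_simulation(cfg, seed = 1)
  expect_equal(unique(run$series$tick), 0L)
  expect_equal(sum(run$series$population), 2 * cfg$n_agents)
})

test_that("initialization matches the documented conditions", {
  cfg <- small_config(n_agents = 10)
  set.seed(3)
  state <- sim_init(cfg)
  ag <- state$agents
  expect_equal(nrow(ag), 20)
  expect_equal(sum(region_of(state$grid, ag$x) == "TianShan"), 10)
  expect_true(all(ag$age >= 1 & ag$age <= 50))
  expect_true(all(ag$energy == cfg$max_energy))
  expect_true(all(ag$body_temp == 37))
  adult <- ag$age >= cfg$adult_age
  expect_true(all(!is.na(ag$trait[adult])))
  expect_true(all(is.na(ag$trait[!adult])))
  expect_equal(sum(state$attractors$active), 4)
})

test_that("a sheltered agent in a mild scenario loses nothing in a tick", {
  cfg <- small_config(n_agents = 0, ticks = 3, reproduction_prob = 0)
  set.seed(4)
  state <- sim_init(cfg)
  att <- state$attractors[1, ]
  state$agents <- as.data.frame(new_agents(1, x = att$x, y = att$y,
                                           energy = 80, body_temp = 34))
  sim_step(state)
  expect_gte(state$agents$energy, 80)
  expect_gte(state$agents$body_temp, 34)
})

test_that("identical config and seed give bit-identical results", {
  cfg <- small_config(ticks = 50, n_agents = 8)
  r1 <- run_simulation(cfg, seed = 17)
  r2 <- run_simulation(cfg, seed = 17)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$attractors, r2$attractors)
  r3 <- run_simulation(cfg, seed = 18)
  expect_false(identical(r1$series, r3$series))
})

test_that("cooperators + defectors + juveniles account for everyone, always", {
  cfg <- small_config(ticks = 80, n_agents = 10)
  run <- run_simulation(cfg, seed = 5)
  s <- run$series
  expect_true(all(s$cooperators + s$defectors + s$juveniles == s$population))
})

test_that("every population change is a logged birth or death", {
  cfg <- small_config(ticks = 80, n_agents = 10)
  run <- run_simulation(cfg, seed = 6)
  tot <- dplyr::summarise(dplyr::group_by(run$series, .data$tick),
                          pop = sum(.data$population))
  ev <- run$events
  for (t in seq_len(max(tot$tick))) {
    births <- sum(ev$event == "birth" & ev$tick == t - 1L)
    deaths <- sum(ev$event == "death" & ev$tick == t - 1L)
    expect_equal(tot$pop[tot$tick == t],
                 tot$pop[tot$tick == t - 1L] + births - deaths)
  }
  # every death carries a cause
  expect_true(all(ev$cause[ev$event == "death"] %in%
                    c("energy", "hypothermia", "age")))
})

test_that("with mortality and reproduction off the population is constant", {
  cfg <- coop_config(width = 30, height = 16, n_attractors_per_region = 2,
                     ticks = 1200, n_agents = 3, mortality = FALSE,
                     reproduction_prob = 0)
  run <- run_simulation(cfg, seed = 7)
  expect_true(all(run$series$population[run$series$region == "TianShan"] +
                    run$series$population[run$series$region == "Altai"] == 6))
})

test_that("agents on depleted patches migrate after the waiting period", {
  # one agent alone on a depleted patch, no shelters, everything else rich
  cfg <- small_config(n_agents = 0, n_attractors_per_region = 0,
                      migration_wait = 3, learning_rate = 0, speed_km = 0,
                      mortality = FALSE, reproduction_prob = 0)
  set.seed(8)
  state <- sim_init(cfg)
  state$grid$resource[] <- state$grid$cap  # rich everywhere ...
  state$grid$resource[10, 10] <- 0         # ... except under the agent
  state$agents <- as.data.frame(new_agents(1, x = 10, y = 10))
  for (i in 1:3) sim_step(state)
  # after migration_wait depleted ticks a destination is set
  expect_false(is.na(state$agents$dest_x))
  frac <- state$grid$resource[cbind(state$agents$dest_y,
                                    state$agents$dest_x)] /
    state$grid$cap[cbind(state$agents$dest_y, state$agents$dest_x)]
  expect_gte(frac, cfg$migration_threshold)

  # a full patch never triggers migration
  set.seed(9)
  state2 <- sim_init(cfg)
  state2$grid$resource[] <- state2$grid$cap
  state2$agents <- as.data.frame(new_agents(1, x = 10, y = 10))
  for (i in 1:6) sim_step(state2)
  expect_true(is.na(state2$agents$dest_x))
  expect_equal(state2$agents$low_res_ticks, 0L)

  # nowhere viable: the agent stays and keeps foraging locally
  set.seed(10)
  state3 <- sim_init(cfg)
  state3$grid$resource[] <- 0
  state3$agents <- as.data.frame(new_agents(1, x = 10, y = 10))
  for (i in 1:6) sim_step(state3)
  expect_true(is.na(state3$agents$dest_x))
})

test_that("extinction pads the series with zeros to the configured length", {
  # no shelters and no resources: certain extinction by energy depletion
  cfg <- small_config(n_attractors_per_region = 0, ticks = 250, n_agents = 4)
  run <- run_simulation(cfg, seed = 11)
  expect_true(run$extinct)
  expect_lt(run$extinction_tick, 250)
  expect_equal(max(run$series$tick), 250)
  late <- run$series[run$series$tick > run$extinction_tick, ]
  expect_true(all(late$population == 0))
})

test_that("runs are tidy: tidy(), glance() and autoplot() work", {
  cfg <- small_config(ticks = 20)
  run <- run_simulation(cfg, seed = 12)
  td <- tidy(run)
  expect_true(all(c("tick", "region", "metric", "value") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_true(is.numeric(gl$final_population))
  expect_s3_class(autoplot(run), "ggplot")
  p <- tempfile(fileext = ".csv")
  write_run_csv(run, p)
  expect_equal(nrow(readr::read_csv(p, show_col_types = FALSE)), nrow(td))
})
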