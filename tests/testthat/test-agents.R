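test_that("body temperature follows the cooling law, warming and death rules", {
  cfg <- small_config(cooling_rate = 0.1)

  # equilibrium: no change when the body already matches a warm environment
  a <- new_agents(1, body_temp = 37)
  expect_equal(update_body_temperature(a, 37, FALSE, cfg)$body_temp, 37)

  # hand-evaluated cooling step: 37 - (37 - (-20)) * 0.1 = 31.3
  a <- new_agents(1, body_temp = 37)
  expect_equal(update_body_temperature(a, -20, FALSE, cfg)$body_temp, 31.3)

  # shelter warms one degree per tick, capped at the normal temperature
  a <- new_agents(2, body_temp = c(35, 37))
  out <- update_body_temperature(a, -20, TRUE, cfg)
  expect_equal(out$body_temp, c(36, 37))

  # falling below 30 deg C is death by hypothermia
  a <- new_agents(1, body_temp = 30.5)
  out <- update_body_temperature(a, -20, FALSE, cfg)
  expect_lt(out$body_temp, 30)
  expect_false(out$alive)
  expect_equal(out$death_cause, "hypothermia")

  cfg_bad <- cfg
  cfg_bad$cooling_rate <- 1.5
  expect_error(update_body_temperature(a, -20, FALSE, cfg_bad),
               "invalid argument")
})

test_that("iterated cooling matches the closed form to 1e-10 over 100 ticks", {
  set.seed(11)
  for (i in 1:20) {
    tc <- runif(1, -40, 5)
    cr <- runif(1, 0.01, 0.95)
    cfg <- small_config(cooling_rate = cr, mortality = FALSE)
    a <- new_agents(1, body_temp = 37)
    for (t in 1:100) a <- update_body_temperature(a, tc, FALSE, cfg)
    expect_equal(a$body_temp, tc + (37 - tc) * (1 - cr)^100,
                 tolerance = 1e-10)
  }
})

test_that("perceived risk is bounded, floored on shelters, monotone in resources", {
  cfg <- small_config()
  grid <- tiny_grid()
  atts <- new_attractors(x = grid$width, y = grid$height, grid = grid)

  # standing on an active shelter: zero risk
  a <- new_agents(1, x = grid$width, y = grid$height)
  expect_equal(perceived_risk(a, grid, atts, cfg), 0)

  # richer local patch means lower risk, all else equal
  g <- grid
  g$resource[5, 5] <- 0.1 * g$cap[5, 5]
  g$resource[5, 6] <- 0.9 * g$cap[5, 6]
  a2 <- new_agents(2, x = c(5, 6), y = c(5, 5))
  r <- perceived_risk(a2, g, atts, cfg)
  expect_gt(r[1], r[2])
  expect_true(all(r >= 0 & r <= 100))

  # worst case: empty patch at maximal distance from the only shelter
  g2 <- grid
  g2$resource[1, 1] <- 0
  a3 <- new_agents(1, x = 1, y = 1)
  expect_equal(perceived_risk(a3, g2, atts, cfg), 100)

  # with no active shelter the patch alone sets the risk
  atts_off <- new_attractors(x = 10, y = 10, active = FALSE, grid = grid)
  a4 <- new_agents(1, x = 1, y = 1)
  expect_equal(perceived_risk(a4, g2, atts_off, cfg), 100)
  g2$resource[1, 1] <- g2$cap[1, 1]
  expect_equal(perceived_risk(a4, g2, atts_off, cfg), 0)
})

test_that("energy depletes with risk, accelerates past the 80% breakpoint", {
  cfg <- small_config()

  # risk 85 depletes faster than risk 50
  a <- new_agents(2, energy = 100)
  out <- update_energy(a, c(85, 50), FALSE, cfg)
  expect_lt(out$energy[1], out$energy[2])
  # above the breakpoint the multiplier is 1 + (risk - 80)/20
  expect_equal(out$energy[1], 100 - cfg$base_energy_cost * 1.25)

  # depleting all energy is death
  a2 <- new_agents(1, energy = 0.5)
  out2 <- update_energy(a2, 0, FALSE, cfg)
  expect_false(out2$alive)
  expect_equal(out2$death_cause, "energy")
  expect_equal(out2$energy, 0)

  # sheltered agents are provisioned from the store, not their own energy
  a3 <- new_agents(1, energy = 100)
  expect_equal(update_energy(a3, 0, TRUE, cfg)$energy, 100)
})

test_that("age cap kills at 50 and the cohort mean death age is 50", {
  cfg <- small_config()
  a <- new_agents(2, age = c(49.99, 20))
  out <- age_step(a, cfg)
  expect_false(out$alive[1])
  expect_equal(out$death_cause[1], "age")
  expect_true(out$alive[2])

  # cohort under the default hard-cap rule: everyone dies within a month
  # of the cap, so the mean death age is inside [49, 51]
  cohort <- new_agents(1000, age = runif(1000, 45, 49.99))
  ages_at_death <- numeric(0)
  for (t in 1:70) {
    cohort <- age_step(cohort, cfg)
    dead <- !cohort$alive
    ages_at_death <- c(ages_at_death, cohort$age[dead])
    cohort <- cohort[!dead, ]
    if (nrow(cohort) == 0) break
  }
  expect_equal(length(ages_at_death), 1000)
  expect_gt(mean(ages_at_death), 49)
  expect_lt(mean(ages_at_death), 51)
})

test_that("the geometric age hazard gives a mean lifespan near 50 years", {
  cfg <- small_config(age_rule = "hazard")
  set.seed(21)
  n <- 4000
  cohort <- new_agents(n, age = 0)
  ages <- numeric(0)
  while (nrow(cohort) > 0) {
    cohort <- age_step(cohort, cfg)
    dead <- !cohort$alive
    ages <- c(ages, cohort$age[dead])
    cohort <- cohort[!dead, ]
  }
  se <- 50 / sqrt(n)
  expect_gt(mean(ages), 50 - 3 * se)
  expect_lt(mean(ages), 50 + 3 * se)
})

test_that("reproduction is gated at age 12 and runs at 10% per tick", {
  cfg <- small_config()

  juv <- new_agents(200, age = 11.9)
  set.seed(5)
  expect_equal(nrow(reproduce(juv, cfg)), 0)

  adults <- new_agents(10000, age = 30)
  set.seed(6)
  babies <- reproduce(adults, cfg)
  p_hat <- nrow(babies) / 10000
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_gt(p_hat, 0.1 - sd3)
  expect_lt(p_hat, 0.1 + sd3)

  # newborn state: parent's position, unset trait, full energy, 37 deg C
  expect_true(all(is.na(babies$trait)))
  expect_true(all(babies$age == 0))
  expect_true(all(babies$energy == cfg$max_energy))
  expect_true(all(babies$body_temp == 37))
  expect_true(all(babies$x == 5 & babies$y == 5))
})

test_that("movement follows targets at the configured speed and stays in-grid", {
  cfg <- small_config()
  grid <- tiny_grid()
  atts <- new_attractors(x = 30, y = 10, grid = grid)

  # an informed agent advances about speed/patch_edge_km patches per tick
  a <- new_agents(1, x = 20, y = 10, knows_path = TRUE, target = 1L)
  out <- move_agents(a, atts, grid, cfg)
  expect_equal(out$x, 20 + round(cfg$speed_km / grid$patch_edge_km))
  expect_equal(out$y, 10)

  # speed zero: no movement at all
  cfg0 <- small_config(speed_km = 0)
  a2 <- new_agents(1, x = 20, y = 10)
  expect_equal(move_agents(a2, atts, grid, cfg0)[, c("x", "y")],
               a2[, c("x", "y")])

  # a naive random walk is reproducible under a fixed seed and stays in-grid
  walk <- function(seed) {
    set.seed(seed)
    a <- new_agents(1, x = 2, y = 2)
    path <- matrix(NA_real_, 30, 2)
    for (i in 1:30) {
      a <- move_agents(a, atts[0, ], grid, cfg)
      path[i, ] <- c(a$x, a$y)
    }
    path
  }
  p1 <- walk(9); p2 <- walk(9)
  expect_identical(p1, p2)
  expect_true(all(p1[, 1] >= 1 & p1[, 1] <= grid$width))
  expect_true(all(p1[, 2] >= 1 & p1[, 2] <= grid$height))

  # an agent already within the occupancy radius of its target stays put
  a3 <- new_agents(1, x = 30, y = 10, knows_path = TRUE, target = 1L)
  out3 <- move_agents(a3, atts, grid, cfg)
  expect_equal(c(out3$x, out3$y), c(30, 10))
})

test_that("path learning is Bernoulli per tick toward the nearest shelter", {
  grid <- tiny_grid()
  atts <- new_attractors(x = c(5, 15, 30), y = c(5, 5, 10), grid = grid)

  cfg1 <- small_config(learning_rate = 1)
  a <- new_agents(1, x = 14, y = 5, knows_path = FALSE)
  out <- learn_paths(a, atts, grid, cfg1)
  expect_true(out$knows_path)
  expect_equal(out$target, 2L)  # nearest active shelter in its region

  cfg0 <- small_config(learning_rate = 0)
  for (i in 1:20) a <- learn_paths(a, atts, grid, cfg0)
  expect_false(a$knows_path)

  cfg25 <- small_config(learning_rate = 0.25)
  naive <- new_agents(10000, x = 10, y = 10, knows_path = FALSE)
  set.seed(31)
  out <- learn_paths(naive, atts, grid, cfg25)
  k <- sum(out$knows_path)
  sd3 <- 3 * sqrt(10000 * 0.25 * 0.75)
  expect_gt(k, 2500 - sd3)
  expect_lt(k, 2500 + sd3)
})
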