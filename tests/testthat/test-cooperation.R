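test_that("payoff components match hand-worked values and edge cases", {
  # e = 1 annihilates both payoffs
  pc <- payoff_components(p = 0.4, n = 12, fail_prob = 1)
  expect_equal(pc$b_c, 0)
  expect_equal(pc$b_d, 0)

  # e = 0, p = 0: cooperators pay the cost, defectors take the punishment
  pc <- payoff_components(p = 0, n = 10, cost = 10, punishment = 7,
                          fail_prob = 0, p1 = 0.2)
  expect_equal(pc$b_c, -10)
  expect_equal(pc$b_d, -10 * 0.2 * 7)

  # worked example: e=0.1, p=0.5, B=20, C=10, rho=7, p1=0.2, N=10
  pc <- payoff_components(p = 0.5, n = 10, benefit = 20, cost = 10,
                          punishment = 7, fail_prob = 0.1, p1 = 0.2)
  expect_equal(pc$b_c, -1.26)
  expect_equal(pc$b_d, -3.6)
})

test_that("the closed-form payoff difference equals the component subtraction", {
  expect_equal(payoff_difference(n = 10, p1 = 0.2, cost = 10, punishment = 7,
                                 fail_prob = 0.1), 2.34)
  expect_equal(payoff_difference(n = 5, p1 = 0.5, fail_prob = 1), 0)
  # e = 0 with defaults: positive iff N p1 > C / rho
  expect_equal(payoff_difference(n = 10, p1 = 0.2, fail_prob = 0),
               10 * 0.2 * 7 - 10)

  # algebraic identity over 1000 random parameter draws
  set.seed(41)
  for (i in 1:1000) {
    p <- runif(1); p1 <- runif(1); e <- runif(1)
    n <- sample.int(200, 1)
    B <- runif(1, 0, 50); C <- runif(1, 0, 50); rho <- runif(1, 0, 20)
    pc <- payoff_components(p, n, B, C, rho, e, p1)
    db <- payoff_difference(n, p1, C, rho, e)
    expect_lt(abs((pc$b_c - pc$b_d) - db), 1e-10)
  }
})

test_that("frequency dynamics have absorbing boundaries and correct limits", {
  # p = 0 and p = 1 are exact fixed points
  expect_identical(delta_p(0, delta_b = 100, alpha = 0.3), 0)
  expect_identical(delta_p(1, delta_b = -100, alpha = 0.3), 0)

  grid_p <- seq(0.01, 0.99, length.out = 100)
  # pure conformity favors the local majority
  dp1 <- delta_p(grid_p, delta_b = 123, alpha = 1)
  expect_equal(sign(dp1), sign(2 * grid_p - 1))
  # pure payoff bias follows the payoff difference
  for (db in c(-3.3, 2.34)) {
    dp0 <- delta_p(grid_p, delta_b = db, alpha = 0, beta = 1)
    expect_true(all(sign(dp0) == sign(db)))
  }

  # hand-worked values
  expect_equal(delta_p(0.7, delta_b = 0, alpha = 1), 0.084)
  expect_equal(delta_p(0.5, delta_b = 2.34, alpha = 0, beta = 1), 0.585)
})

test_that("mean-field iteration from p = 0.8 with favorable payoffs rises to 1", {
  p <- 0.8
  prev <- p
  for (i in 1:2000) {
    p <- min(1, p + delta_p(p, delta_b = 10))
    expect_gte(p, prev)
    prev <- p
  }
  expect_gt(p, 0.99)
})

test_that("initial traits are Bernoulli for adults and unset for juveniles", {
  a <- new_agents(10, age = 30, trait = NA)
  a$age[1] <- 5  # one juvenile
  out0 <- assign_initial_traits(a, 0)
  expect_true(all(out0$trait[-1] == 0L))
  out1 <- assign_initial_traits(a, 1)
  expect_true(all(out1$trait[-1] == 1L))
  expect_true(is.na(out0$trait[1]) && is.na(out1$trait[1]))

  big <- new_agents(10000, age = 30, trait = NA)
  set.seed(51)
  share <- mean(assign_initial_traits(big, 0.8)$trait)
  sd3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_gt(share, 0.8 - sd3)
  expect_lt(share, 0.8 + sd3)
})

test_that("the three-stage strategy update switches the expected numbers", {
  # all channels off: nothing changes
  cfg <- small_config(alpha = 0, prob_nocoop = 0)
  a <- new_agents(10, x = 1:10, y = 1, trait = rep(c(0L, 1L), 5))
  out <- update_strategies(a, dp = 0, cfg)
  expect_identical(out$trait, a$trait)

  # drift: dp = +0.25 with 10 adults switches 2 or 3 defectors,
  # 2.5 in expectation (stochastic rounding of 0.25 * 10)
  cfg <- small_config(alpha = 0, prob_nocoop = 0)
  set.seed(61)
  switched <- replicate(2000, {
    a <- new_agents(10, x = seq(1, 37, length.out = 10), y = 1, trait = 0L)
    sum(update_strategies(a, dp = 0.25, cfg)$trait)
  })
  expect_true(all(switched %in% c(2L, 3L)))
  expect_lt(abs(mean(switched) - 2.5), 3 * 0.5 / sqrt(2000))

  # forced defection empties the cooperator pool in one tick
  cfg <- small_config(alpha = 0, prob_nocoop = 1)
  a <- new_agents(10, trait = 1L)
  expect_true(all(update_strategies(a, 0, cfg)$trait == 0L))

  # conformity: a lone defector amid clustered cooperators flips with
  # probability alpha = 1
  cfg <- small_config(alpha = 1, prob_nocoop = 0)
  a <- new_agents(5, x = c(10, 10, 11, 11, 10), y = c(10, 11, 10, 11, 12),
                  trait = c(1L, 1L, 1L, 1L, 0L))
  out <- update_strategies(a, 0, cfg)
  expect_equal(out$trait[5], 1L)
})

test_that("strategy updates conserve heads and keep frequencies in [0, 1]", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample.int(40, 1) + 2L
    cfg <- small_config(alpha = runif(1), prob_nocoop = runif(1, 0, 0.1))
    a <- new_agents(n, x = sample.int(40, n, TRUE), y = sample.int(20, n, TRUE),
                    trait = sample(0:1, n, TRUE))
    out <- update_strategies(a, runif(1, -0.5, 0.5), cfg)
    expect_equal(nrow(out), n)
    expect_true(all(out$trait %in% c(0L, 1L)))
    p <- mean(out$trait)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("juveniles reaching adulthood adopt the surrounding majority", {
  cfg <- small_config()
  grid <- tiny_grid()
  # four cooperators around a juvenile who just turned 12
  a <- new_agents(5, x = c(10, 10, 11, 11, 10), y = c(10, 11, 10, 11, 12),
                  trait = c(1L, 1L, 1L, 1L, NA), age = c(30, 30, 30, 30, 12.01))
  out <- coopclim:::adopt_traits(a, grid, cfg)
  expect_equal(out$trait[5], 1L)

  # no neighbors: Bernoulli(prob_cooperation) fallback
  cfg1 <- small_config(prob_cooperation = 1)
  b <- new_agents(1, x = 10, y = 10, trait = NA, age = 12.01)
  expect_equal(coopclim:::adopt_traits(b, grid, cfg1)$trait, 1L)
})
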