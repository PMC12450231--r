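#' Cooperator and defector payoffs
#'
#' The public-goods payoff structure with punishment:
#' `b_c = (1 - e) * (p*B*(1 - e) - C + e*(p*B - N*p1*rho))` and
#' `b_d = (1 - e) * (p*B - N*p1*rho)`, where `p` is the cooperator frequency,
#' `B` the group benefit, `C` the cost of cooperation, `rho` the punishment,
#' `p1` the punisher frequency, `e` the probability of failing in cooperation
#' and `N` the number of individuals.
#'
#' @param p Cooperator frequency in `[0, 1]` (vectorized).
#' @param n Number of individuals (vectorized).
#' @param benefit Group benefit B.
#' @param cost Cost of cooperation C.
#' @param punishment Punishment rho.
#' @param fail_prob Probability e of failing in cooperation.
#' @param p1 Punisher frequency; defaults to the cooperator frequency.
#' @return A tibble with columns `b_c` and `b_d`.
#' @export
#' @examples
#' payoff_components(p = 0.5, n = 10, benefit = 20, fail_prob = 0.1, p1 = 0.2)
payoff_components <- function(p, n, benefit = 20, cost = 10, punishment = 7,
                              fail_prob = 0.1, p1 = p) {
  e <- fail_prob
  common <- p * benefit - n * p1 * punishment
  tibble::tibble(
    b_c = (1 - e) * (p * benefit * (1 - e) - cost + e * common),
    b_d = (1 - e) * common
  )
}

#' Payoff difference between cooperators and defectors
#'
#' Closed form of `b_c - b_d`:
#' `delta_b = (1 - e) * (N * p1 * (1 - e) * rho - C)`. Algebraically identical
#' to subtracting the [payoff_components()] columns.
#'
#' @inheritParams payoff_components
#' @return Numeric vector of payoff differences.
#' @export
#' @examples
#' payoff_difference(n = 10, p1 = 0.2, fail_prob = 0.1)  # 2.34
payoff_difference <- function(n, p1, cost = 10, punishment = 7,
                              fail_prob = 0.1) {
  e <- fail_prob
  (1 - e) * (n * p1 * (1 - e) * punishment - cost)
}

#' Change in cooperator frequency (conformist-transmission dynamics)
#'
#' `delta_p = p*(1 - p) * ((1 - alpha)*beta*delta_b + alpha*(2p - 1))`:
#' payoff-biased copying weighted `(1 - alpha)` against conformist copying of
#' the local majority weighted `alpha`. The boundaries p = 0 and p = 1 are
#' fixed points; the caller clamps `p + delta_p` into `[0, 1]`.
#'
#' @param p Cooperator frequency in `[0, 1]` (vectorized).
#' @param delta_b Payoff difference from [payoff_difference()].
#' @param alpha Strength of conformist transmission in `[0, 1]`.
#' @param beta Normalization of the payoff term (> 0).
#' @return Numeric vector of frequency changes.
#' @export
#' @examples
#' delta_p(0.7, delta_b = 0, alpha = 1)  # pure conformity: +0.084
delta_p <- function(p, delta_b, alpha = 0.2, beta = 0.01) {
  stopifnot(all(p >= 0 & p <= 1), alpha >= 0, alpha <= 1, beta >= 0)
  p * (1 - p) * ((1 - alpha) * beta * delta_b + alpha * (2 * p - 1))
}

#' Assign initial strategy traits
#'
#' Each living adult independently cooperates (trait 1) with probability
#' `prob` and defects (trait 0) otherwise; juveniles (age below `adult_age`)
#' keep an unset trait.
#'
#' @param agents Agent tibble.
#' @param prob Initial cooperator probability.
#' @param adult_age Adult age threshold in years.
#' @return The updated agents.
#' @export
assign_initial_traits <- function(agents, prob, adult_age = 12) {
  stopifnot(prob >= 0, prob <= 1)
  adult <- agents$alive & agents$age >= adult_age
  agents$trait[adult] <- as.integer(runif(sum(adult)) < prob)
  agents
}

#' Apply the per-tick strategy update to one region's adults
#'
#' Realizes the frequency dynamics at the agent level in three stages:
#' \enumerate{
#'   \item \emph{Evolutionary drift}: randomly chosen adults of the
#'     disfavored strategy switch toward `sign(dp)`; the number of switchers
#'     is `|dp| * N` stochastically rounded (floor plus a Bernoulli draw on
#'     the fraction), so the realized flow matches the frequency equation in
#'     expectation even at small N. The simulator passes the payoff-biased
#'     part of the frequency change here; the conformist part is realized
#'     spatially by stage 2, so no channel is counted twice.
#'   \item \emph{Local conformity}: each adult whose neighborhood (radius
#'     `radius_strategy` patches, Euclidean, excluding self) holds a strict
#'     majority of the opposite strategy switches with probability `alpha`;
#'     majorities are evaluated simultaneously. Ties exert no pressure.
#'   \item \emph{Spontaneous defection}: each cooperator defects with
#'     probability `prob_nocoop`.
#' }
#' The adult head count is conserved; only traits change.
#'
#' @param agents Agent tibble (one region's agents; all rows are treated as
#'   one population).
#' @param dp Frequency change driving stage 1, already clamped by the caller.
#' @param config A [coop_config()].
#' @return The updated agents.
#' @export
update_strategies <- function(agents, dp, config) {
  adults <- which(agents$alive & !is.na(agents$trait))
  if (length(adults) == 0) return(agents)
  agents$trait[adults] <- strategy_kernel(
    agents$trait[adults], agents$x[adults], agents$y[adults], dp, config
  )
  agents
}

# vectorized three-stage trait update on one region's adult traits
strategy_kernel <- function(tr, x, y, dp, config) {
  n <- length(tr)

  # stage 1: drift toward the favored strategy; stochastic rounding keeps
  # the expected number of switchers at |dp| * n exactly
  if (!is.na(dp) && dp != 0) {
    flow <- abs(dp) * n
    k <- floor(flow) + (runif(1) < flow - floor(flow))
    from <- if (dp > 0) which(tr == 0L) else which(tr == 1L)
    k <- min(k, length(from))
    if (k > 0) {
      pick <- if (length(from) == 1) from else sample(from, k)
      tr[pick] <- if (dp > 0) 1L else 0L
    }
  }

  # stage 2: conformity pressure from the radius neighborhood
  if (config$alpha > 0 && n > 1) {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    diag(d2) <- Inf
    nb <- d2 <= config$radius_strategy^2
    n_coop <- as.vector(nb %*% (tr == 1L))
    n_def <- as.vector(nb %*% (tr == 0L))
    pressured <- (tr == 1L & n_def > n_coop) | (tr == 0L & n_coop > n_def)
    switch <- pressured & runif(n) < config$alpha
    tr[switch] <- 1L - tr[switch]
  }

  # stage 3: spontaneous defection
  if (config$prob_nocoop > 0) {
    co <- which(tr == 1L)
    drop <- co[runif(length(co)) < config$prob_nocoop]
    tr[drop] <- 0L
  }
  tr
}

# Trait adoption for agents crossing the adult age: copy the strict majority
# among trait-bearing neighbors within the strategy radius of the same
# region; with no neighbors (or a tie) fall back to Bernoulli(prob).
adopt_traits <- function(agents, grid, config) {
  newly <- which(agents$alive & is.na(agents$trait) &
                   agents$age >= config$adult_age)
  if (length(newly) == 0) return(agents)
  adults <- which(agents$alive & !is.na(agents$trait))
  reg_new <- region_of(grid, agents$x[newly])
  for (i in seq_along(newly)) {
    a <- newly[i]
    nb <- adults[region_of(grid, agents$x[adults]) == reg_new[i]]
    if (length(nb) > 0) {
      d2 <- (agents$x[nb] - agents$x[a])^2 + (agents$y[nb] - agents$y[a])^2
      nb <- nb[d2 <= config$radius_strategy^2]
    }
    if (length(nb) > 0) {
      nc <- sum(agents$trait[nb] == 1L)
      nd <- length(nb) - nc
      if (nc != nd) {
        agents$trait[a] <- as.integer(nc > nd)
        next
      }
    }
    agents$trait[a] <- as.integer(runif(1) < config$prob_cooperation)
  }
  agents
}
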