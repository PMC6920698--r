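test_that("reaction set matches the ODE fluxes after omega conversion", {
  set.seed(61)
  for (i in 1:5) {
    p <- random_params()
    omega <- sample(c(1, 50, 1000), 1)
    net <- build_reactions(p, omega)
    x <- random_state()
    tfa <- stats::runif(1, 0, 300)
    a <- net$propensity(x * omega, tfa)
    d <- digitalizer_derivatives(x, p, tfa)
    flux <- drop(a %*% net$stoichiometry) / omega
    expect_equal(unname(flux), unname(d), tolerance = 1e-10)
  }
  # stoichiometry: pairing removes exactly one of each RNA
  S <- build_reactions(digitalizer_params(), 1)$stoichiometry
  expect_equal(unname(S[5, ]), c(-1, -1, 0, 0))
  # all-zero rates give zero total propensity in any state
  p0 <- digitalizer_params(alpha_R = 0, beta_R = 0, alpha_S = 0, k_pair = 0,
                           delta_mR = 0, delta_mS = 0, delta_R = 0,
                           delta_G = 0, lambda_R = 0, lambda_G = 0)
  a0 <- build_reactions(p0, 1)$propensity(c(mR = 5, mS = 5, R = 5, G = 5), 100)
  expect_equal(sum(a0), 0)
})

test_that("zero-propensity systems stay constant; same stream reproduces", {
  p0 <- digitalizer_params(alpha_R = 0, beta_R = 0, alpha_S = 0, k_pair = 0,
                           delta_mR = 0, delta_mS = 0, delta_R = 0,
                           delta_G = 0, lambda_R = 0, lambda_G = 0)
  out <- gillespie(p0, 100, t_max = 50, init = c(mR = 3, mS = 2, R = 1, G = 9),
                   snapshot_times = c(0, 25, 50), seed = 5)
  expect_true(all(out$snapshots$mR == 3 & out$snapshots$G == 9))

  p <- digitalizer_params()
  a <- gillespie(p, 1000, t_max = 3, seed = 9, cell_index = 4,
                 record_trajectory = TRUE)
  b <- gillespie(p, 1000, t_max = 3, seed = 9, cell_index = 4,
                 record_trajectory = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  c_ <- gillespie(p, 1000, t_max = 3, seed = 9, cell_index = 5,
                  record_trajectory = TRUE)
  expect_false(identical(a$trajectory, c_$trajectory))
})

test_that("frozen birth-death subsystem reaches the Poisson stationary law", {
  # all channels off except G translation (rate a = lambda_G * mR) and decay d:
  # stationary G ~ Poisson(a/d), so mean = variance = a/d
  bd <- digitalizer_params(alpha_R = 0, beta_R = 0, alpha_S = 0, k_pair = 0,
                           delta_mR = 0, delta_mS = 0, delta_R = 0,
                           delta_G = 0.1, lambda_R = 0, lambda_G = 2)
  pop <- simulate_population(bd, 0, snapshot_times = 120, n_cells = 500,
                             init = c(mR = 10, mS = 0, R = 0, G = 0), seed = 17)
  m <- 2 * 10 / 0.1
  se_mean <- sqrt(m / 500)
  se_var <- m * sqrt(2 / 499)
  expect_lt(abs(mean(pop$G) - m), 3 * se_mean)
  expect_lt(abs(stats::var(pop$G) - m), 3 * se_var)
  # counts stay non-negative integers through long runs
  expect_true(all(pop$G >= 0 & pop$G == floor(pop$G)))
})

test_that("trajectories are piecewise constant and states are integer counts", {
  p <- digitalizer_params()
  out <- gillespie(p, 500, t_max = 2, omega = 10, seed = 2,
                   record_trajectory = TRUE)
  tr <- out$trajectory
  expect_true(all(diff(tr$time) >= 0))
  expect_true(all(as.matrix(tr[, -1]) == floor(as.matrix(tr[, -1]))))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  # each event changes the state by one reaction's stoichiometry
  S <- build_reactions(p, 10)$stoichiometry
  jumps <- diff(as.matrix(tr[, c("mR", "mS", "R", "G")]))
  legal <- apply(jumps, 1, function(j) any(apply(S, 1, function(s) all(s == j))))
  expect_true(all(legal))
})

test_that("population means converge to the ODE as omega grows", {
  # at saturating inducer, far from the switching threshold where transition-
  # timing noise would dominate
  p <- digitalizer_params()
  tc <- simulate_ode(p, 1000, times = c(0, 3, 6))
  g_ode <- tc$G[tc$time == 6]
  devs <- vapply(c(100, 1000, 10000), function(om) {
    pop <- simulate_population(p, 1000, snapshot_times = 6, n_cells = 30,
                               omega = om, seed = 23)
    abs(mean(pop$G) / om - g_ode) / g_ode
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("single-cell and population paths agree for n_cells = 1", {
  p <- digitalizer_params()
  one <- gillespie(p, 200, t_max = 5, omega = 20, seed = 31, cell_index = 1,
                   snapshot_times = c(0, 2.5, 5))
  pop <- simulate_population(p, 200, snapshot_times = c(0, 2.5, 5),
                             n_cells = 1, omega = 20, seed = 31)
  expect_equal(unname(as.matrix(one$snapshots[, c("mR", "mS", "R", "G")])),
               unname(as.matrix(pop[, c("mR", "mS", "R", "G")])))
})

test_that("only the digitalized construct maintains an uninduced toxin gene", {
  # one-hit lethality amplifies basal leak: over an hour, the digitalized
  # circuit keeps most uninduced cells alive, the leaky parent keeps none -
  # and both kill completely on full induction
  doses <- c(0, 1000)
  dig <- one_hit_survival(digitalizer_params(), doses, t_max = 60,
                          n_cells = 300, seed = 41)
  nd <- one_hit_survival(construct_params("non_digitalized"), doses,
                         t_max = 60, n_cells = 300, seed = 41)
  # nd survivors at dose 0 are the rare cells that fire no transcript at all
  # (or whose transcripts are never translated): P ~ exp(-beta_R * t) ~ 2%
  expect_gte(dig$survival[dig$dose == 0], 0.5)
  expect_lte(nd$survival[nd$dose == 0], 0.06)
  expect_gt(dig$survival[dig$dose == 0], 10 * nd$survival[nd$dose == 0])
  expect_equal(dig$survival[dig$dose == 1000], 0)
  expect_equal(nd$survival[nd$dose == 1000], 0)
})

test_that("induced populations carry positive G variance", {
  p <- digitalizer_params()
  pop <- simulate_population(p, 1000, snapshot_times = 30, n_cells = 30,
                             omega = 10, seed = 37)
  expect_gt(stats::var(pop$G), 0)
})
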