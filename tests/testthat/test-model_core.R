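test_that("Hill activation and repression take their defining values", {
  expect_equal(hill_activation(0, K = 5, n = 2), 0)
  expect_equal(hill_activation(5, K = 5, n = 2), 0.5)
  expect_equal(hill_activation(5, K = 5, n = 7), 0.5)
  expect_equal(hill_activation(10, K = 5, n = 2), 100 / 125)
  expect_equal(hill_repression(0, K = 1, n = 2), 1)
  expect_equal(hill_repression(1, K = 1, n = 3), 0.5)
  expect_equal(hill_repression(3, K = 1, n = 2), 0.1)
  # monotonicity
  x <- seq(0, 100, length.out = 50)
  expect_true(all(diff(hill_activation(x, 20, 2)) >= 0))
  expect_true(all(diff(hill_repression(x, 20, 2)) <= 0))
  # domain errors
  expect_error(hill_activation(-1, 5, 2), "non-negative")
  expect_error(hill_activation(NaN, 5, 2))
  expect_error(hill_activation(1, 0, 2), "positive")
  expect_error(hill_activation(1, 5, 0.5), ">= 1")
})

test_that("activation and repression are complementary to 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    r <- stats::runif(1, 0, 1000)
    K <- stats::runif(1, 1, 500)
    n <- sample(1:4, 1)
    expect_equal(hill_repression(r, K, n) + hill_activation(r, K, n), 1,
                 tolerance = 1e-12)
  }
})

test_that("derivatives have the stated zero-state limit and pairing symmetry", {
  p <- digitalizer_params(beta_R = 0)
  d <- digitalizer_derivatives(c(mR = 0, mS = 0, R = 0, G = 0), p, tf_a = 30)
  expect_equal(d[["mR"]], p$alpha_R * hill_activation(30, p$K_TF, p$n_act))
  expect_equal(d[["mS"]], p$alpha_S)
  expect_equal(d[["R"]], 0)
  expect_equal(d[["G"]], 0)

  # the pairing loss enters dmR and dmS with identical magnitude
  set.seed(21)
  for (i in 1:10) {
    pp <- random_params(k_pair = stats::runif(1, 0.1, 3))
    p0 <- do.call(digitalizer_params,
                  utils::modifyList(unclass(pp), list(k_pair = 0)))
    s <- random_state()
    tfa <- stats::runif(1, 0, 500)
    dk <- digitalizer_derivatives(s, pp, tfa)
    d0 <- digitalizer_derivatives(s, p0, tfa)
    expect_equal(dk[["mR"]] - d0[["mR"]], dk[["mS"]] - d0[["mS"]],
                 tolerance = 1e-12)
    expect_equal(dk[["mR"]] - d0[["mR"]], -pp$k_pair * s[["mR"]] * s[["mS"]],
                 tolerance = 1e-12)
  }
  expect_error(digitalizer_derivatives(c(mR = -1, mS = 0, R = 0, G = 0), p, 1),
               "non-negative")
})

test_that("closed-form unpaired steady state zeroes the derivatives", {
  set.seed(31)
  for (i in 1:10) {
    p <- random_params(k_pair = 0)
    tfa <- stats::runif(1, 0, 500)
    ss <- steady_state_unpaired(p, tfa)
    d <- digitalizer_derivatives(ss, p, tfa)
    expect_lt(max(abs(d)), 1e-9 * (1 + max(abs(ss))))
  }
  # hand-checked values
  p <- digitalizer_params(beta_R = 2, alpha_R = 0, delta_mR = 1, k_pair = 0)
  expect_equal(steady_state_unpaired(p, 0)[["mR"]], 2)
  p2 <- digitalizer_params(alpha_R = 0, beta_R = 0, k_pair = 0)
  ss2 <- steady_state_unpaired(p2, 100)
  expect_equal(unname(ss2[c("mR", "R", "G")]), c(0, 0, 0))
  expect_equal(ss2[["mS"]], p2$alpha_S / p2$delta_mS)
  # guards
  expect_error(steady_state_unpaired(digitalizer_params(), 0), "k_pair")
  expect_error(steady_state_unpaired(
    digitalizer_params(k_pair = 0, delta_mS = 0), 0), "decay")
})

test_that("dynamics are homogeneous under concentration rescaling", {
  # scaling concentrations and Ks by c, rates alpha/beta by c and k_pair by
  # 1/c leaves trajectories identical up to the scale factor
  set.seed(41)
  for (i in 1:5) {
    p <- random_params(k_pair = stats::runif(1, 0.1, 2))
    cfac <- stats::runif(1, 2, 20)
    p_sc <- do.call(digitalizer_params, utils::modifyList(unclass(p), list(
      alpha_R = p$alpha_R * cfac, beta_R = p$beta_R * cfac,
      K_TF = p$K_TF * cfac, alpha_S = p$alpha_S * cfac, K_R = p$K_R * cfac,
      k_pair = p$k_pair / cfac)))
    s <- random_state()
    tfa <- stats::runif(1, 0, 300)
    d1 <- digitalizer_derivatives(s, p, tfa)
    d2 <- digitalizer_derivatives(s * cfac, p_sc, tfa * cfac)
    expect_equal(unname(d2), unname(d1 * cfac), tolerance = 1e-10)
  }
})

test_that("the non-negative orthant is forward-invariant at its boundary", {
  set.seed(51)
  for (i in 1:10) {
    p <- random_params()
    s <- random_state()
    tfa <- stats::runif(1, 0, 300)
    for (sp in c("mR", "mS", "R", "G")) {
      s0 <- s; s0[[sp]] <- 0
      expect_gte(digitalizer_derivatives(s0, p, tfa)[[sp]], 0)
    }
  }
})

test_that("inducer protocols validate and evaluate correctly", {
  pr <- inducer_protocol(c(0, 60, 120), c(0, 1000, 0))
  expect_equal(digitalizer:::protocol_level_at(pr, c(0, 59.9, 60, 119, 120, 500)),
               c(0, 0, 1000, 1000, 0, 0))
  expect_error(inducer_protocol(c(0, 0), c(1, 2)), "increasing")
  expect_error(inducer_protocol(0, -1), "non-negative")
})
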