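test_that("fluorescence model reduces to the deterministic affine map", {
  nm <- noise_model(gain = 2, sigma_ext = 0, autofluor_mu = log(50),
                    autofluor_sigma = 0, floor = 1)
  au <- fluorescence_model(c(0, 0, 0), nm, seed = 1)
  expect_equal(au, rep(50, 3))
  # floor clipping
  nm2 <- noise_model(gain = 2, sigma_ext = 0, autofluor_mu = log(0.1),
                     autofluor_sigma = 0, floor = 1)
  expect_equal(fluorescence_model(0, nm2), 1)
  expect_error(fluorescence_model(-1, nm), "non-negative")
})

test_that("doubling the gain doubles the autofluorescence-subtracted signal", {
  nm1 <- noise_model(gain = 1, sigma_ext = 0.3, autofluor_sigma = 0,
                     autofluor_mu = log(10), floor = 0)
  nm2 <- noise_model(gain = 2, sigma_ext = 0.3, autofluor_sigma = 0,
                     autofluor_mu = log(10), floor = 0)
  G <- c(5, 50, 500)
  a1 <- fluorescence_model(G, nm1, seed = 7) - 10
  a2 <- fluorescence_model(G, nm2, seed = 7) - 10
  expect_equal(a2, 2 * a1)
})

test_that("sample mean matches the lognormal mean identity", {
  nm <- noise_model(gain = 3, sigma_ext = 0.4, autofluor_mu = log(80),
                    autofluor_sigma = 0.5, floor = 0)
  n <- 1e5
  au <- fluorescence_model(rep(100, n), nm, seed = 11)
  expected <- 3 * 100 * exp(0.4^2 / 2) + exp(log(80) + 0.5^2 / 2)
  se <- stats::sd(au) / sqrt(n)
  expect_lt(abs(mean(au) - expected), 3 * se)
})

test_that("noiseless pipeline preserves the ordering of per-cell G", {
  nm <- noise_model(gain = 2, sigma_ext = 0, autofluor_sigma = 0)
  p <- digitalizer_params()
  pop <- simulate_population(p, 1000, snapshot_times = 20, n_cells = 50,
                             omega = 5, seed = 3)
  au <- fluorescence_model(pop$G, nm, seed = 1)
  expect_equal(order(au), order(pop$G))
})

test_that("event tables have the designed structure and round-trip via CSV", {
  design <- flow_design(doses = c(0, 1000), times = c(0, 60))
  ev <- generate_flow_experiment(design, n_events = 40, seed = 5)
  expect_s3_class(ev, "event_table")
  counts <- dplyr::count(ev, construct, dose, time)
  expect_true(all(counts$n == 40))
  expect_equal(nrow(counts), nrow(design))

  path <- tempfile(fileext = ".csv")
  write_event_csv(ev, path)
  back <- read_event_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ev[names(back)]),
               ignore_attr = TRUE)

  expect_error(generate_flow_experiment(
    tibble::tibble(construct = "mystery", dose = 0, time = 0)), "mystery")
})

test_that("promoterless rows are pure autofluorescence at every time", {
  design <- flow_design(constructs = "promoterless", doses = 0,
                        times = c(0, 60, 1440))
  nm <- noise_model()
  ev <- generate_flow_experiment(design, n_events = 4000, noise = nm, seed = 9)
  # medians near the autofluorescence median, independent of time
  med <- tapply(ev$fluorescence, ev$time, stats::median)
  expect_true(all(abs(med / exp(nm$autofluor_mu) - 1) < 0.05))
})

test_that("basal medians digitalize: OFF construct sits on the control", {
  design <- flow_design(doses = 0, times = c(60, 1440))
  ev <- generate_flow_experiment(design, n_events = 4000, seed = 13)
  med <- function(cn, tt) {
    stats::median(ev$fluorescence[ev$construct == cn & ev$time == tt])
  }
  # digitalized basal within 10% of the promoterless control at both times
  for (tt in c(60, 1440)) {
    expect_lt(abs(med("digitalized", tt) / med("promoterless", tt) - 1), 0.1)
    # non-digitalized basal leak is well above the control
    expect_gt(med("non_digitalized", tt), 1.5 * med("promoterless", tt))
  }
  # and the closed form says why: basal mR* = beta_R / delta_mR > 0
  p <- construct_params("non_digitalized")
  expect_gt(p$beta_R / p$delta_mR, 0)
})

test_that("plate-reader output normalises growth out of the signal", {
  design <- flow_design(constructs = c("digitalized", "promoterless"),
                        doses = c(0, 1000), times = c(0, 240, 480))
  pr <- generate_platereader(design, seed = 3)
  expect_true(all(c("od600", "fluorescence", "fluorescence_per_od")
                  %in% names(pr)))
  # zero expression: per-OD fluorescence equals the autofluorescence constant
  ctl <- pr[pr$construct == "promoterless", ]
  expect_equal(stats::sd(ctl$fluorescence_per_od), 0, tolerance = 1e-8)
  # normalisation identity: scaling OD leaves fluorescence_per_od unchanged
  expect_equal(ctl$fluorescence / ctl$od600, ctl$fluorescence_per_od)
  # dose-ranked terminal response for the digitalized construct
  dig <- pr[pr$construct == "digitalized" & pr$time == 480, ]
  expect_true(all(diff(dig$fluorescence_per_od[order(dig$dose)]) > 0))
})
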