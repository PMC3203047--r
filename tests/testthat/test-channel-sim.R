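test_that("a single-level (or absorbing) model yields one covering segment", {
  one <- channel_model(conductance_level("open", 1000))
  p <- sample_state_path(one, 42, seed = 1)
  expect_identical(nrow(p), 1L)
  expect_equal(p$start_s, 0)
  expect_equal(p$end_s, 42)

  # level 1 absorbing among several levels is permissible, not an error
  absorbing <- channel_model(
    list(conductance_level("a", 500), conductance_level("b", 100)),
    matrix(c(0, 0, 3, 0), nrow = 2, byrow = TRUE))
  p2 <- sample_state_path(absorbing, 5, seed = 1)
  expect_identical(nrow(p2), 1L)
  expect_equal(p2$end_s, 5)
})

test_that("dwell times and occupancy match exponential/stationary theory", {
  m <- channel_model(
    list(conductance_level("a", 1000), conductance_level("b", 500)),
    matrix(c(0, 10, 10, 0), nrow = 2, byrow = TRUE))
  p <- sample_state_path(m, 1000, seed = 202)
  dwell <- p$end_s - p$start_s
  n <- length(dwell)
  # exponential dwell with rate 10 -> mean 0.1, within 3 standard errors
  expect_lt(abs(mean(dwell) - 0.1), 3 * 0.1 / sqrt(n))
  occ0 <- sum(dwell[p$level == 1L]) / 1000
  expect_lt(abs(occ0 - 0.5), 0.03)
  # segments are contiguous and cover [0, duration]
  expect_equal(p$start_s[-1L], p$end_s[-nrow(p)])
  expect_true(all(dwell > 0))
})

test_that("stochastic outputs are bit-reproducible given the seed", {
  m <- tic20_channel_model()
  expect_identical(sample_state_path(m, 5, seed = 9),
                   sample_state_path(m, 5, seed = 9))
  p <- sample_state_path(m, 1, seed = 9)
  prot <- voltage_protocol("step", 100, 100, 1)
  sym <- buffer_condition(250)
  t1 <- suppressWarnings(render_current(p, m, prot, sym, 5000, seed = 3))
  t2 <- suppressWarnings(render_current(p, m, prot, sym, 5000, seed = 3))
  t3 <- suppressWarnings(render_current(p, m, prot, sym, 5000, seed = 4))
  expect_identical(t1, t2)
  expect_false(identical(t1$current_pA, t3$current_pA))
  pars <- swelling_params(seed = 5)
  expect_identical(simulate_swelling(pars), simulate_swelling(pars))
})

test_that("GHK reversal is zero under symmetry, monotone in r, Nernst-bounded", {
  asym <- buffer_condition(250, 20, 293.15)
  expect_identical(ghk_reversal_mV(6.5, buffer_condition(250, 250)), 0)
  expect_identical(ghk_reversal_mV(1, asym), 0)
  rs <- c(0.1, 0.5, 1, 2, 6.5, 20, 1e3, 1e6)
  es <- vapply(rs, ghk_reversal_mV, numeric(1), buffer = asym)
  expect_true(all(diff(es) > 0))
  expect_true(all(es < nernst_potential_mV(250, 20, 1, 293.15)))
})

test_that("rendering obeys Ohm's law and reverses exactly at E_rev", {
  ohmic <- channel_model(conductance_level("open", 1000))
  sym <- buffer_condition(250)
  p <- sample_state_path(ohmic, 1, seed = 1)
  tr <- render_current(p, ohmic, voltage_protocol("step", 100, 100, 1),
                       sym, 1000, seed = 1)
  expect_equal(tr$current_pA, rep(100, 1000))

  sel <- channel_model(conductance_level("open", 1000),
                       permeability_ratio = 6.5)
  asym <- buffer_condition(250, 20, 293.15)
  e_rev <- ghk_reversal_mV(6.5, asym)
  ramp <- render_current(sample_state_path(sel, 1, seed = 1), sel,
                         voltage_protocol("ramp", -100, 100, 1), asym,
                         2000, seed = 1)
  neg <- ramp$voltage_mV[ramp$current_pA < 0]
  pos <- ramp$voltage_mV[ramp$current_pA > 0]
  expect_lt(max(neg), e_rev)
  expect_gte(min(pos), e_rev)
})

test_that("stationary_distribution solves pi Q = 0 (2-state analytic case)", {
  # k12 = 2, k21 = 6 -> pi = (k21, k12)/(k12 + k21) = (0.75, 0.25)
  expect_equal(
    stationary_distribution(matrix(c(0, 2, 6, 0), nrow = 2, byrow = TRUE)),
    c(0.75, 0.25))
})

test_that("swelling simulation reproduces channel-free and channel traces", {
  flat <- simulate_swelling(swelling_params(
    recovery_rate_per_min = 0, noise_sd_od = 0, seed = 1))
  post <- flat$time_min >= flat$salt_time_min
  expect_equal(unique(flat$od500[post]), 0.1 * (1 - 0.2))
  expect_equal(unique(flat$od500[!post]), 0.1)

  rec <- simulate_swelling(swelling_params(
    recovery_rate_per_min = 0.05, noise_sd_od = 0, seed = 1))
  post <- rec$time_min >= rec$salt_time_min
  expect_true(all(diff(rec$od500[post]) > 0))
  expect_true(all(rec$od500[post] < 0.1))   # asymptote is the baseline
  expect_lt(0.1 - rec$od500[sum(post)], 0.2 * 0.1)  # recovering toward it
})

test_that("model validation rejects malformed inputs", {
  lev <- list(conductance_level("a", 100), conductance_level("b", 50))
  expect_error(channel_model(lev, matrix(0, 3, 3)), "2x2")
  expect_error(channel_model(lev, matrix(c(0, -1, 2, 0), 2, 2)), ">= 0")
  expect_error(channel_model(lev, matrix(0, 2, 2), permeability_ratio = 0),
               "permeability_ratio")
  expect_error(conductance_level("a", -5), ">= 0")
  expect_error(buffer_condition(0, 20), "> 0")
  expect_error(buffer_condition(250, 20, temperature_K = 350), "273.15")
  expect_error(voltage_protocol("step", 10, 20, 1), "v_start_mV == v_end_mV")
})
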