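test_that("noise estimate is robust to level steps", {
  expect_equal(estimate_noise_sd(make_step_trace(rep(7, 500), 50)), 0)
  expect_error(estimate_noise_sd(rep(1, 50)), "100 samples")

  x <- withr::with_seed(10, rnorm(1e5, sd = 2))
  expect_lt(abs(estimate_noise_sd(x) / 2 - 1), 0.05)

  # add ~100 large level steps: robust estimate unmoved, naive sd inflates
  stepped <- x + rep(rep(c(0, 100), each = 1000), length.out = 1e5)
  expect_lt(abs(estimate_noise_sd(stepped) / 2 - 1), 0.05)
  expect_gt(sd(stepped), 10)
})

test_that("noiseless square wave idealizes exactly; constant trace is one segment", {
  x <- rep(rep_len(c(0, 10), 11L), each = 40L)  # 10 transitions
  id <- idealize_trace(make_step_trace(x, 100, 2000))
  expect_identical(nrow(id$segments), 11L)
  expect_equal(id$segments$mean_pA, rep_len(c(0, 10), 11L))
  expect_equal(id$segments$start, seq(1L, 401L, by = 40L))

  noisy <- withr::with_seed(2, rnorm(2000, mean = 30, sd = 2))
  idc <- idealize_trace(make_step_trace(noisy, 100, 2000))
  expect_identical(nrow(idc$segments), 1L)
  expect_equal(idc$segments$mean_pA, mean(noisy))
})

test_that("ramp traces are rejected by the idealizer", {
  ramp <- make_ramp_trace(rep(0, 400), -100, 100, 0.4)
  expect_error(idealize_trace(ramp), "unsupported protocol")
})

test_that(">= 95% of large well-separated transitions are recovered, few spurious", {
  sq <- square_wave_trace(n_transitions = 200, amplitude_pA = 12,
                          noise_sd = 2, rate_Hz = 5000, seed = 31)
  id <- idealize_trace(sq$trace, idealization_params(threshold_k = 4,
                                                     min_dwell_s = 0.001))
  found <- id$segments$start[-1L]
  near <- function(b) any(abs(found - b) <= 2L)
  hit <- vapply(sq$boundaries, near, logical(1))
  expect_gte(mean(hit), 0.95)
  spurious <- vapply(found, function(b) all(abs(sq$boundaries - b) > 2L),
                     logical(1))
  expect_lte(mean(spurious), 0.02)
})

test_that("idealization is idempotent on its own reconstruction", {
  sq <- square_wave_trace(n_transitions = 50, seed = 7)
  id <- idealize_trace(sq$trace)
  recon <- make_step_trace(reconstruct_current(id), 100, 5000)
  id2 <- idealize_trace(recon)
  expect_equal(id2$segments$start, id$segments$start)
  expect_equal(id2$segments$mean_pA, id$segments$mean_pA)
})

test_that("lowering the detection threshold never loses true transitions", {
  sq <- square_wave_trace(n_transitions = 100, amplitude_pA = 10, seed = 13)
  hits <- function(k) {
    id <- idealize_trace(sq$trace, idealization_params(threshold_k = k))
    found <- id$segments$start[-1L]
    sum(vapply(sq$boundaries, function(b) any(abs(found - b) <= 2L),
               logical(1)))
  }
  expect_gte(hits(3), hits(4))
  expect_gte(hits(4), hits(5))
})

test_that("gating events carry the unit-checked conductance and polarity", {
  # single clean 10 pA step at +100 mV, symmetric buffer -> 100 pS, positive
  x <- c(rep(0, 500), rep(10, 500)) +
    withr::with_seed(4, rnorm(1000, sd = 0.5))
  tr <- make_step_trace(x, 100, 1000)
  id <- idealize_trace(tr)
  ev <- extract_gating_events(id, tr)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$conductance_pS, 100, tolerance = 0.02)
  expect_identical(ev$polarity, "positive")
  expect_gt(ev$delta_I_pA, 0)
  expect_equal(ev$dwell_pre_s, 0.5)

  # one segment -> no events
  flat <- make_step_trace(withr::with_seed(5, rnorm(500, 20, 1)), -80)
  expect_identical(nrow(extract_gating_events(idealize_trace(flat), flat)),
                   0L)

  # events within 10 mV of the assumed reversal are dropped
  lowv <- make_step_trace(x, 5, 1000)
  expect_identical(
    nrow(extract_gating_events(idealize_trace(lowv), lowv)), 0L)

  # mismatched idealization/trace pair is refused
  expect_error(extract_gating_events(id, flat), "does not match")
})

test_that("event count equals segment transitions minus low-voltage drops", {
  sq <- square_wave_trace(n_transitions = 40, seed = 21, v_mV = 100)
  id <- idealize_trace(sq$trace)
  ev <- extract_gating_events(id, sq$trace)
  expect_identical(nrow(ev), nrow(id$segments) - 1L)
})
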