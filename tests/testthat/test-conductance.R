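events_df <- function(conductance_pS, polarity, voltage_mV = NULL,
                      delta_I_pA = NULL) {
  n <- length(conductance_pS)
  data.frame(
    time_s = seq_len(n), voltage_mV = voltage_mV %||% rep(100, n),
    delta_I_pA = delta_I_pA %||% rep(1, n),
    conductance_pS = conductance_pS, polarity = polarity,
    dwell_pre_s = rep(0.1, n), dwell_post_s = rep(0.1, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("class assignment applies the polarity-specific thresholds", {
  ev <- events_df(c(250, 100, 220, 179.9, 180),
                  c("negative", "positive", "negative", "positive",
                    "positive"))
  out <- assign_classes(ev, class_defs(220, 180))
  expect_identical(out$class_id, c("II", "I", "II", "I", "II"))
  # partition: every event assigned exactly one class
  expect_false(anyNA(out$class_id))
  expect_true(all(out$class_id %in% c("I", "II")))
  expect_error(
    assign_classes(events_df(50, "positive"),
                   data.frame(polarity = "negative", threshold_pS = 220)),
    "no class definition")
})

test_that("histogram bins are right-open, conserve counts, locate modes", {
  ev <- events_df(c(30, 60, 60, 400), rep("negative", 4))
  h <- conductance_histogram(ev, "negative", 50)
  expect_equal(h$bin_edges_pS, seq(0, 450, by = 50))
  expect_identical(h$counts,
                   c(1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(sum(h$counts), 4L)

  # conservation under arbitrary widths (property)
  g <- withr::with_seed(8, runif(500, 5, 700))
  pol <- withr::with_seed(9, sample(c("negative", "positive"), 500, TRUE))
  ev2 <- events_df(g, pol)
  for (wdt in c(10, 25, 50, 117)) {
    expect_identical(sum(conductance_histogram(ev2, "negative", wdt)$counts),
                     sum(pol == "negative"))
  }
  # an event sitting exactly on an edge falls into the upper bin
  h2 <- conductance_histogram(events_df(100, "positive"), "positive", 50)
  expect_identical(h2$counts, c(0L, 0L, 1L))

  h0 <- conductance_histogram(events_df(numeric(0), character(0)),
                              "negative", 25)
  expect_identical(h0$n_events, 0L)
  expect_length(h0$counts, 0L)
})

test_that("per-class I-V fits recover an exact line and skip singletons", {
  v <- c(-140, -100, -60, 60, 100, 140)
  ev <- events_df(rep(300, 6),
                  ifelse(v < 0, "negative", "positive"),
                  voltage_mV = v, delta_I_pA = 0.3 * v)
  ev <- assign_classes(ev)
  fits <- fit_class_iv(ev)
  expect_identical(nrow(fits), 2L)  # class II at both polarities
  expect_equal(fits$slope_conductance_pS, c(300, 300))
  expect_equal(fits$r_squared, c(1, 1))
  expect_equal(fits$intercept_pA, c(0, 0), tolerance = 1e-10)

  lone <- assign_classes(events_df(50, "positive", voltage_mV = 80,
                                   delta_I_pA = 4))
  expect_warning(f2 <- fit_class_iv(lone), "skipped")
  expect_identical(nrow(f2), 0L)
  expect_error(fit_class_iv(events_df(50, "positive")), "classified")
})

test_that("I-V slopes are invariant to event order and duplication", {
  withr::with_seed(12, {
    v <- sample(c(-140, -100, -60, 60, 100, 140), 60, TRUE)
    g <- sample(c(150, 350), 60, TRUE) + rnorm(60, sd = 5)
  })
  ev <- assign_classes(events_df(g, ifelse(v < 0, "negative", "positive"),
                                 voltage_mV = v,
                                 delta_I_pA = sign(v) * g * v / 1000))
  base <- fit_class_iv(ev)
  shuf <- fit_class_iv(ev[withr::with_seed(13, sample(nrow(ev))), ])
  dup <- fit_class_iv(rbind(ev, ev))
  expect_equal(shuf$slope_conductance_pS, base$slope_conductance_pS)
  expect_equal(dup$slope_conductance_pS, base$slope_conductance_pS)
  expect_identical(dup$n_events, 2L * base$n_events)
})

test_that("fully open conductance: exact ohmic case and polarity precondition", {
  mk_ideal <- function(v, g_pS) {
    idealize_trace(make_step_trace(rep(g_pS * v / 1000, 300), v, 1000,
                                   trace_id = paste0("v", v)))
  }
  ideals <- lapply(c(-100, -60, -20, 20, 60, 100), mk_ideal, g_pS = 1000)
  tg <- fully_open_conductance(ideals)
  expect_equal(tg$g_neg_pS, 1000)
  expect_equal(tg$g_pos_pS, 1000)
  expect_equal(tg$se_neg_pS, 0, tolerance = 1e-9)
  expect_identical(unname(tg$n_voltages), c(3L, 3L))

  expect_error(
    fully_open_conductance(lapply(c(-100, -60, -20), mk_ideal, g_pS = 1000)),
    "3 voltages at each polarity")
})
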