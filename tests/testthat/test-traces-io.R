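test_that("a minimal step-protocol file reads into a validated trace", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(write_tiny_trace_lines(), f)
  tr <- read_trace(f)
  expect_s3_class(tr, "current_trace")
  expect_length(tr$current_pA, 3L)
  expect_equal(tr$voltage_mV, rep(100, 3))
  expect_equal(tr$current_pA, rep(10, 3))
  expect_equal(tr$buffer$kcl_cis_mM, 250)
  expect_equal(tr$protocol$kind, "step")
  expect_identical(tr$trace_id, "tiny")
})

test_that("format errors name the offending key, cell and line", {
  lines <- write_tiny_trace_lines()
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(lines[-5L], f)  # drop the ph header
  expect_error(read_trace(f), "missing mandatory header key 'ph'")

  bad <- lines
  bad[14L] <- "0.001\t100\toops"  # second data row
  writeLines(bad, f)
  expect_error(read_trace(f), "non-numeric value 'oops'.*line 14")

  bad <- lines
  bad[14L] <- "0.001\t55\t10"  # voltage varies during a declared step
  writeLines(bad, f)
  expect_error(read_trace(f), "voltage column inconsistent")
})

test_that("write/read round trip is the identity at stored precision", {
  f <- withr::local_tempfile(fileext = ".tsv")
  for (seed in 1:4) {
    kind <- if (seed %% 2L) "step" else "ramp"
    n <- 500L
    rate <- 2500
    x <- withr::with_seed(seed, {
      v0 <- if (kind == "step") 70 else -100
      v1 <- if (kind == "step") 70 else 100
      t <- (seq_len(n) - 1) / rate
      current_trace(
        time_s = t,
        current_pA = rnorm(n, mean = 50, sd = 2),
        voltage_mV = if (kind == "step") rep(v0, n) else
          v0 + t / (n / rate) * (v1 - v0),
        sample_rate_Hz = rate,
        buffer = buffer_condition(250, 20, 295.65, 7.2),
        protocol = voltage_protocol(kind, v0, v1, n / rate),
        trace_id = paste0("rt-", seed),
        extra_header = c(operator = "qc"))
    })
    y <- read_trace(write_trace(x, f))
    z <- read_trace(write_trace(y, f))
    # one write/read cycle is a fixed point ...
    expect_identical(y, z)
    # ... and stays within the stored decimal precision of the original
    expect_lt(max(abs(y$current_pA - x$current_pA)),
              1e-5 * max(abs(x$current_pA)))
    expect_lt(max(abs(y$voltage_mV - x$voltage_mV)), 0.5)
    expect_identical(y$trace_id, x$trace_id)
    expect_equal(y$buffer, x$buffer)
    expect_equal(y$protocol, x$protocol)
    expect_identical(y$extra_header[["operator"]], "qc")
  }
})

test_that("writing an invalid or empty trace is refused", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- structure(list(time_s = numeric(0), current_pA = numeric(0),
                          voltage_mV = numeric(0), sample_rate_Hz = 1000,
                          buffer = buffer_condition(250),
                          protocol = voltage_protocol("step", 10, 10, 1),
                          trace_id = "empty", extra_header = character(0)),
                     class = "current_trace")
  expect_error(write_trace(empty, f), "0 samples")
})

test_that("validate_trace reports diagnostics without raising or mutating", {
  tr <- make_step_trace(rep(5, 200), 80)
  expect_identical(validate_trace(tr), character(0))

  bad <- tr
  bad$current_pA[5L] <- NaN
  expect_match(validate_trace(bad), "current_pA.*index 5")
  expect_identical(bad$current_pA[5L], NaN)  # input untouched

  ramp <- make_ramp_trace(rep(0, 400), -100, 100, 0.4)
  pert <- ramp
  pert$voltage_mV[200L] <- pert$voltage_mV[200L] + 1  # > 0.5 mV off-affine
  expect_match(validate_trace(pert), "voltage column inconsistent with ramp")
})

test_that("simulated traces satisfy the trace invariants (cross-module)", {
  model <- tic20_channel_model()
  sym <- buffer_condition(250)
  asym <- buffer_condition(250, 20)
  step <- suppressWarnings(
    render_current(sample_state_path(model, 0.5, seed = 3), model,
                   voltage_protocol("step", -100, -100, 0.5), sym,
                   5000, seed = 4))
  ramp <- suppressWarnings(
    render_current(sample_state_path(model, 0.5, seed = 5), model,
                   voltage_protocol("ramp", -100, 100, 0.5), asym,
                   5000, seed = 6))
  expect_identical(validate_trace(step), character(0))
  expect_identical(validate_trace(ramp), character(0))
})
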