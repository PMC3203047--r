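# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

make_step_trace <- function(current_pA, v_mV, rate_Hz = 1000,
                            buffer = buffer_condition(250),
                            trace_id = "fixture") {
  n <- length(current_pA)
  current_trace(
    time_s = (seq_len(n) - 1) / rate_Hz, current_pA = current_pA,
    voltage_mV = rep(v_mV, n), sample_rate_Hz = rate_Hz, buffer = buffer,
    protocol = voltage_protocol("step", v_mV, v_mV, n / rate_Hz),
    trace_id = trace_id)
}

make_ramp_trace <- function(current_pA, v_from, v_to, dur_s,
                            buffer = buffer_condition(250, 20),
                            trace_id = "ramp-fixture") {
  n <- length(current_pA)
  rate <- n / dur_s
  t <- (seq_len(n) - 1) / rate
  current_trace(
    time_s = t, current_pA = current_pA,
    voltage_mV = v_from + t / dur_s * (v_to - v_from),
    sample_rate_Hz = rate, buffer = buffer,
    protocol = voltage_protocol("ramp", v_from, v_to, dur_s),
    trace_id = trace_id)
}

# Two-level square wave with random dwells and Gaussian noise; returns the
# trace plus the ground-truth boundary sample indices (start of each new
# segment).
square_wave_trace <- function(n_transitions = 200, amplitude_pA = 12,
                              noise_sd = 2, rate_Hz = 5000,
                              dwell_range = c(50L, 250L), seed = 1,
                              v_mV = 100) {
  withr::with_seed(seed, {
    dwells <- sample(dwell_range[1L]:dwell_range[2L], n_transitions + 1L,
                     replace = TRUE)
    levels <- rep_len(c(0, amplitude_pA), n_transitions + 1L)
    x <- rep(levels, dwells) + rnorm(sum(dwells), sd = noise_sd)
  })
  list(trace = make_step_trace(x, v_mV, rate_Hz),
       boundaries = head(cumsum(dwells), -1L) + 1L,
       dwells = dwells, levels = levels)
}

# Simulated multi-voltage step fixture with retained ground-truth paths.
sim_step_fixture <- function(model, voltages_mV, duration_s, rate_Hz,
                             master_seed, buffer = buffer_condition(250)) {
  out <- lapply(seq_along(voltages_mV), function(i) {
    v <- voltages_mV[i]
    path <- sample_state_path(model, duration_s,
                              seed = master_seed + 2L * i)
    trace <- suppressWarnings(render_current(
      path, model, voltage_protocol("step", v, v, duration_s), buffer,
      rate_Hz, seed = master_seed + 2L * i + 1L,
      trace_id = sprintf("step_%+d", v)))
    list(path = path, trace = trace)
  })
  list(paths = lapply(out, `[[`, "path"),
       traces = lapply(out, `[[`, "trace"),
       voltages_mV = voltages_mV)
}

write_tiny_trace_lines <- function() {
  c("# format_version=1",
    "# trace_id=tiny",
    "# sample_rate_hz=1000",
    "# temperature_k=293.15",
    "# ph=7",
    "# kcl_cis_mm=250",
    "# kcl_trans_mm=250",
    "# protocol=step",
    "# v_start_mv=100",
    "# v_end_mv=100",
    "# duration_s=0.003",
    "time_s\tvoltage_mv\tcurrent_pa",
    "0\t100\t10",
    "0.001\t100\t10",
    "0.002\t100\t10")
}
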