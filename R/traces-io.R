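# Trace containers and the on-disk trace format.
#
# Project-wide units: current pA, potential mV, conductance pS, time s,
# concentration mM, temperature K. Sign convention: the potential is that of
# the cis (sample-addition) chamber relative to trans, and positive current
# is cation flow cis -> trans; a cation-selective channel with the high-salt
# side cis therefore reverses at a positive potential.

VOLTAGE_TOL_MV <- 0.5  # tolerance for protocol/voltage-column consistency

#' Recording buffer condition
#'
#' Ionic and thermal metadata of a bilayer recording: the KCl concentration on
#' each side of the membrane, the absolute temperature and the pH. These are
#' the quantities entering the Goldman-Hodgkin-Katz and Nernst relations.
#'
#' @param kcl_cis_mM KCl concentration in the cis chamber (mM).
#' @param kcl_trans_mM KCl concentration in the trans chamber (mM); defaults
#'   to the cis value (symmetric buffer).
#' @param temperature_K absolute temperature (K), restricted to
#'   \[273.15, 323.15\].
#' @param ph bath pH (metadata only; no computation uses it).
#' @return An object of class `"buffer_condition"`.
#' @examples
#' buffer_condition(250, 20)          # asymmetric, 250/20 mM KCl
#' buffer_condition(250)              # symmetric 250 mM KCl
#' @export
buffer_condition <- function(kcl_cis_mM, kcl_trans_mM = kcl_cis_mM,
                             temperature_K = 293.15, ph = 7.0) {
  check_scalar_number(kcl_cis_mM, "kcl_cis_mM", positive = TRUE)
  check_scalar_number(kcl_trans_mM, "kcl_trans_mM", positive = TRUE)
  check_scalar_number(temperature_K, "temperature_K")
  check_scalar_number(ph, "ph")
  if (temperature_K < 273.15 || temperature_K > 323.15)
    stop_invalid("'temperature_K' outside [273.15, 323.15]")
  structure(
    list(kcl_cis_mM = as.numeric(kcl_cis_mM),
         kcl_trans_mM = as.numeric(kcl_trans_mM),
         temperature_K = as.numeric(temperature_K),
         ph = as.numeric(ph)),
    class = "buffer_condition")
}

is_symmetric_buffer <- function(buffer) {
  isTRUE(all.equal(buffer$kcl_cis_mM, buffer$kcl_trans_mM))
}

#' @export
print.buffer_condition <- function(x, ...) {
  cat(sprintf("KCl %g/%g mM (cis/trans), %.2f K, pH %g\n",
              x$kcl_cis_mM, x$kcl_trans_mM, x$temperature_K, x$ph))
  invisible(x)
}

#' Voltage protocol
#'
#' A constant-voltage step (`v_start_mV == v_end_mV`) or a linear voltage ramp
#' applied over `duration_s` seconds.
#'
#' @param kind `"step"` or `"ramp"`.
#' @param v_start_mV,v_end_mV command potential at the start/end (mV). For a
#'   step the two must be equal (`v_end_mV` defaults to `v_start_mV`).
#' @param duration_s protocol duration (s), > 0.
#' @return An object of class `"voltage_protocol"`.
#' @export
voltage_protocol <- function(kind = c("step", "ramp"), v_start_mV,
                             v_end_mV = v_start_mV, duration_s) {
  kind <- match.arg(kind)
  check_scalar_number(v_start_mV, "v_start_mV")
  check_scalar_number(v_end_mV, "v_end_mV")
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  if (kind == "step" && v_start_mV != v_end_mV)
    stop_invalid("step protocol requires v_start_mV == v_end_mV")
  structure(
    list(kind = kind, v_start_mV = as.numeric(v_start_mV),
         v_end_mV = as.numeric(v_end_mV), duration_s = as.numeric(duration_s)),
    class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  if (x$kind == "step")
    cat(sprintf("step at %+g mV for %g s\n", x$v_start_mV, x$duration_s))
  else
    cat(sprintf("ramp %+g -> %+g mV over %g s\n",
                x$v_start_mV, x$v_end_mV, x$duration_s))
  invisible(x)
}

#' Single-channel current trace
#'
#' A uniformly sampled current recording together with its per-sample command
#' potential, sampling rate, buffer condition and voltage protocol. The
#' constructor validates all invariants (see [validate_trace()]) and refuses
#' inconsistent input.
#'
#' @param time_s sample times (s), uniformly spaced.
#' @param current_pA sampled current (pA).
#' @param voltage_mV per-sample command potential (mV); constant for a step
#'   protocol, affine in time for a ramp.
#' @param sample_rate_Hz sampling rate (Hz).
#' @param buffer a [buffer_condition()].
#' @param protocol a [voltage_protocol()].
#' @param trace_id identifier string.
#' @param extra_header named character vector of additional metadata carried
#'   through the file format untouched.
#' @return An object of class `"current_trace"`.
#' @seealso [read_trace()], [write_trace()], [validate_trace()]
#' @export
current_trace <- function(time_s, current_pA, voltage_mV, sample_rate_Hz,
                          buffer, protocol, trace_id = "trace",
                          extra_header = character(0)) {
  x <- structure(
    list(time_s = as.numeric(time_s),
         current_pA = as.numeric(current_pA),
         voltage_mV = as.numeric(voltage_mV),
         sample_rate_Hz = as.numeric(sample_rate_Hz),
         buffer = buffer, protocol = protocol,
         trace_id = as.character(trace_id),
         extra_header = extra_header),
    class = "current_trace")
  problems <- validate_trace(x)
  if (length(problems))
    stop_invalid("invalid trace: ", paste(problems, collapse = "; "))
  x
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace '%s': %d samples at %g Hz\n",
              x$trace_id, length(x$current_pA), x$sample_rate_Hz))
  print(x$protocol)
  print(x$buffer)
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  plot(x$time_s, x$current_pA, type = "l", xlab = "time (s)",
       ylab = "current (pA)", main = x$trace_id, ...)
  invisible(x)
}

#' Validate a current trace
#'
#' Diagnostic check of every trace invariant: equal series lengths, finite
#' values, uniform sample spacing consistent with the stated rate, a voltage
#' column consistent with the declared protocol (constant for a step, affine
#' in time for a ramp, both within 0.5 mV), and coverage of the protocol
#' duration. Returns messages rather than raising, so it can be used to
#' screen files of unknown provenance; the [current_trace()] constructor
#' raises on any violation.
#'
#' @param trace an object shaped like a `current_trace` (not necessarily
#'   valid).
#' @return Character vector of violated invariants; `character(0)` if the
#'   trace is valid. The input is never modified.
#' @export
validate_trace <- function(trace) {
  msgs <- character(0)
  n <- length(trace$time_s)
  if (length(trace$current_pA) != n || length(trace$voltage_mV) != n)
    return("time_s, current_pA and voltage_mV must have equal lengths")
  if (n == 0L)
    return("trace has 0 samples")
  for (nm in c("time_s", "current_pA", "voltage_mV")) {
    bad <- which(!is.finite(trace[[nm]]))
    if (length(bad))
      msgs <- c(msgs, sprintf("%s contains a non-finite value at index %d",
                              nm, bad[1L]))
  }
  if (length(msgs)) return(msgs)
  if (!is.numeric(trace$sample_rate_Hz) || length(trace$sample_rate_Hz) != 1L ||
      !is.finite(trace$sample_rate_Hz) || trace$sample_rate_Hz <= 0)
    return(c(msgs, "sample_rate_Hz must be a positive number"))
  dt_nom <- 1 / trace$sample_rate_Hz
  if (n >= 2L) {
    dev <- abs(diff(trace$time_s) - dt_nom)
    if (any(dev > dt_nom * 1e-6 + 1e-9))
      msgs <- c(msgs, sprintf(
        "sample spacing not uniform at the stated rate (first violation near index %d)",
        which(dev > dt_nom * 1e-6 + 1e-9)[1L]))
  }
  if (!inherits(trace$protocol, "voltage_protocol")) {
    msgs <- c(msgs, "protocol is not a voltage_protocol")
  } else {
    p <- trace$protocol
    v_exp <- if (p$kind == "step") {
      rep(p$v_start_mV, n)
    } else {
      p$v_start_mV + (trace$time_s - trace$time_s[1L]) / p$duration_s *
        (p$v_end_mV - p$v_start_mV)
    }
    dv <- abs(trace$voltage_mV - v_exp)
    if (any(dv > VOLTAGE_TOL_MV))
      msgs <- c(msgs, sprintf(
        "voltage column inconsistent with %s protocol (deviation %.3g mV at index %d)",
        p$kind, max(dv), which.max(dv)))
    if (abs(n / trace$sample_rate_Hz - p$duration_s) > 2 * dt_nom)
      msgs <- c(msgs, "trace length inconsistent with protocol duration")
  }
  if (!inherits(trace$buffer, "buffer_condition"))
    msgs <- c(msgs, "buffer is not a buffer_condition")
  msgs
}

MANDATORY_HEADER_KEYS <- c(
  "format_version", "trace_id", "sample_rate_hz", "temperature_k", "ph",
  "kcl_cis_mm", "kcl_trans_mm", "protocol", "v_start_mv", "v_end_mv",
  "duration_s")

#' Read a current trace from a TSV file
#'
#' The trace format is UTF-8 tab-separated text: header lines of the form
#' `# key=value` (mandatory keys: `format_version`, `trace_id`,
#' `sample_rate_hz`, `temperature_k`, `ph`, `kcl_cis_mm`, `kcl_trans_mm`,
#' `protocol`, `v_start_mv`, `v_end_mv`, `duration_s`), then a column header
#' `time_s<TAB>voltage_mv<TAB>current_pa`, then one row per sample. One trace
#' per file. Unknown header keys are preserved in `extra_header`.
#'
#' @param path path to a trace file.
#' @return A validated [current_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop_invalid("trace file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  head_lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln))
      stop_invalid("format error: no data section in ", path)
    if (startsWith(ln, "#")) head_lines <- c(head_lines, ln) else break
  }
  col_line <- ln
  close(con)
  on.exit()

  body <- sub("^#[[:space:]]*", "", head_lines)
  has_eq <- grepl("=", body, fixed = TRUE)
  if (any(!has_eq))
    stop_invalid("format error: header line without key=value: '",
                 head_lines[which(!has_eq)[1L]], "'")
  keys <- sub("=.*$", "", body)
  vals <- sub("^[^=]*=", "", body)
  header <- stats::setNames(trimws(vals), trimws(keys))
  missing <- setdiff(MANDATORY_HEADER_KEYS, names(header))
  if (length(missing))
    stop_invalid("format error: missing mandatory header key '",
                 missing[1L], "'")

  num_key <- function(nm) {
    v <- suppressWarnings(as.numeric(header[[nm]]))
    if (is.na(v))
      stop_invalid("format error: header key '", nm, "' is not numeric ('",
                   header[[nm]], "')")
    v
  }
  kind <- header[["protocol"]]
  if (!kind %in% c("step", "ramp"))
    stop_invalid("format error: header key 'protocol' must be 'step' or 'ramp'")

  cols <- strsplit(col_line, "\t", fixed = TRUE)[[1L]]
  if (!identical(cols, c("time_s", "voltage_mv", "current_pa")))
    stop_invalid("format error: expected column header ",
                 "'time_s\tvoltage_mv\tcurrent_pa'")
  dat <- data.table::fread(path, skip = length(head_lines), sep = "\t",
                           header = TRUE, data.table = FALSE)
  for (nm in names(dat)) {
    col <- dat[[nm]]
    if (!is.numeric(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(conv))[1L]
      stop_invalid(sprintf(
        "format error: non-numeric value '%s' in column '%s' at line %d",
        col[bad], nm, length(head_lines) + 1L + bad))
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop_invalid(sprintf(
        "format error: missing value in column '%s' at line %d",
        nm, length(head_lines) + 1L + bad))
    }
  }

  extra <- header[setdiff(names(header), MANDATORY_HEADER_KEYS)]
  current_trace(
    time_s = dat$time_s,
    current_pA = dat$current_pa,
    voltage_mV = dat$voltage_mv,
    sample_rate_Hz = num_key("sample_rate_hz"),
    buffer = buffer_condition(num_key("kcl_cis_mm"), num_key("kcl_trans_mm"),
                              num_key("temperature_k"), num_key("ph")),
    protocol = voltage_protocol(kind, num_key("v_start_mv"),
                                num_key("v_end_mv"), num_key("duration_s")),
    trace_id = header[["trace_id"]],
    extra_header = extra)
}

#' Write a current trace to a TSV file
#'
#' Inverse of [read_trace()]: emits the `# key=value` header, the column
#' header and the data rows. Current is stored to 6 significant digits and
#' voltage to 3 (both below recording noise); time is stored to full
#' precision. Round-trip `read_trace(write_trace(x))` is the identity at the
#' stored precision.
#'
#' @param trace a valid [current_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  problems <- validate_trace(trace)
  if (length(problems))
    stop_invalid("refusing to write invalid trace: ",
                 paste(problems, collapse = "; "))
  hdr <- c(
    "# format_version=1",
    sprintf("# trace_id=%s", trace$trace_id),
    sprintf("# sample_rate_hz=%.17g", trace$sample_rate_Hz),
    sprintf("# temperature_k=%.17g", trace$buffer$temperature_K),
    sprintf("# ph=%.17g", trace$buffer$ph),
    sprintf("# kcl_cis_mm=%.17g", trace$buffer$kcl_cis_mM),
    sprintf("# kcl_trans_mm=%.17g", trace$buffer$kcl_trans_mM),
    sprintf("# protocol=%s", trace$protocol$kind),
    sprintf("# v_start_mv=%.17g", trace$protocol$v_start_mV),
    sprintf("# v_end_mv=%.17g", trace$protocol$v_end_mV),
    sprintf("# duration_s=%.17g", trace$protocol$duration_s))
  if (length(trace$extra_header))
    hdr <- c(hdr, sprintf("# %s=%s", names(trace$extra_header),
                          trace$extra_header))
  hdr <- c(hdr, "time_s\tvoltage_mv\tcurrent_pa")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  dat <- data.frame(time_s = trace$time_s,
                    voltage_mv = signif(trace$voltage_mV, 3L),
                    current_pa = signif(trace$current_pA, 6L))
  data.table::fwrite(dat, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

# Results tables share the trace format's "# key=value" provenance header.
write_result_tsv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  if (length(header))
    writeLines(sprintf("# %s=%s", names(header), as.character(header)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  close(con)
  if (nrow(df))
    data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}
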