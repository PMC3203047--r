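# Trace idealization: noise estimation, piecewise-constant segmentation and
# gating-event extraction.
#
# Detection is a two-pass scheme: (1) candidate change points wherever the
# difference between the means of adjacent sliding windows exceeds
# threshold_k * sigma, refined to the sample of maximal local difference
# within each candidate run; (2) segments shorter than the minimum dwell are
# merged into the neighbour with the closer mean, and adjacent segments whose
# means differ by less than the detection threshold are merged, until stable.

#' Idealization parameters
#'
#' @param threshold_k step-detection threshold as a multiple of the noise SD
#'   (default 4; with ~2 pA noise this puts ~25 pS events at the detection
#'   edge for |V| = 100 mV).
#' @param min_dwell_s minimum resolvable dwell (s, default 1 ms); it also
#'   sets the sliding-window width.
#' @param e_rev_assumed_mV reversal potential used to convert event
#'   amplitudes to conductances; 0 for symmetric-buffer recordings.
#' @return An object of class `"idealization_params"`.
#' @export
idealization_params <- function(threshold_k = 4, min_dwell_s = 0.001,
                                e_rev_assumed_mV = 0) {
  check_scalar_number(threshold_k, "threshold_k", positive = TRUE)
  check_scalar_number(min_dwell_s, "min_dwell_s", positive = TRUE)
  check_scalar_number(e_rev_assumed_mV, "e_rev_assumed_mV")
  structure(list(threshold_k = threshold_k, min_dwell_s = min_dwell_s,
                 e_rev_assumed_mV = e_rev_assumed_mV),
            class = "idealization_params")
}

#' Robust recording-noise estimate
#'
#' Median absolute deviation of the first differences of the current,
#' divided by `sqrt(2) * 0.6745`. Level steps affect only a vanishing
#' fraction of the differences, so the estimate is insensitive to gating,
#' unlike the naive standard deviation.
#'
#' @param trace a [current_trace()] (or a bare numeric current vector) with
#'   at least 100 samples.
#' @return Estimated noise standard deviation (pA).
#' @export
estimate_noise_sd <- function(trace) {
  x <- if (inherits(trace, "current_trace")) trace$current_pA else
    as.numeric(trace)
  if (length(x) < 100L)
    stop_invalid("noise estimation needs >= 100 samples (got ", length(x), ")")
  d <- diff(x)
  stats::mad(d, constant = 1) / (sqrt(2) * 0.6745)
}

segment_means <- function(cs, starts, n) {
  ends <- c(starts[-1L] - 1L, n)
  (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
}

#' Idealize a step-protocol current trace
#'
#' Reduces a noisy constant-voltage recording to a piecewise-constant
#' sequence of current levels. Every true step of amplitude at least
#' `threshold_k * sigma` lasting at least `min_dwell_s` is represented;
#' shorter segments are merged into the neighbour with the closer mean.
#' Deterministic, and idempotent on its own piecewise-constant
#' reconstruction. Ramp traces are rejected.
#'
#' @param trace a step-protocol [current_trace()].
#' @param params an [idealization_params()].
#' @return An object of class `"idealized_trace"`: a `segments` data frame
#'   (`start`, `end` exclusive, `n_samples`, `dwell_s`, `mean_pA`), the
#'   source `trace_id`, the step voltage, the estimated noise SD and the
#'   parameters used.
#' @export
idealize_trace <- function(trace, params = idealization_params()) {
  if (!inherits(trace, "current_trace"))
    stop_invalid("'trace' must be a current_trace")
  if (trace$protocol$kind != "step")
    stop_invalid("unsupported protocol: only step traces are idealized")
  x <- trace$current_pA
  n <- length(x)
  w <- max(1L, as.integer(round(params$min_dwell_s * trace$sample_rate_Hz)))
  if (n < max(100L, 2L * w + 1L))
    stop_invalid("trace too short to idealize (", n, " samples)")
  sigma <- estimate_noise_sd(trace)
  # floor the threshold at the cumulative-sum round-off scale so that a
  # noiseless (or reconstructed) trace does not flag floating-point jitter
  thr <- max(params$threshold_k * sigma, 1e-8 * max(abs(x), 1))
  cs <- c(0, cumsum(x))

  # pass 1: candidate boundaries from adjacent sliding-window mean difference
  b <- (w + 1L):(n - w + 1L)  # boundary = first index of the right window
  d <- (cs[b + w] - cs[b]) / w - (cs[b] - cs[b - w]) / w
  cand <- which(abs(d) > thr)
  cps <- integer(0)
  if (length(cand)) {
    run_id <- cumsum(c(1L, diff(cand) != 1L))
    cps <- vapply(split(cand, run_id), function(r) r[which.max(abs(d[r]))],
                  integer(1)) + w
  }
  starts <- sort(unique(c(1L, cps)))

  # pass 2: merge sub-min-dwell segments (into the closer-mean neighbour),
  # then adjacent segments whose means differ by less than the threshold
  repeat {
    if (length(starts) == 1L) break
    len <- diff(c(starts, n + 1L))
    means <- segment_means(cs, starts, n)
    short <- which(len < w)
    if (length(short)) {
      i <- short[which.min(len[short])]
      if (i == 1L) {
        drop <- 2L
      } else if (i == length(starts)) {
        drop <- i
      } else {
        drop <- if (abs(means[i] - means[i - 1L]) <=
                    abs(means[i] - means[i + 1L])) i else i + 1L
      }
      starts <- starts[-drop]
      next
    }
    dm <- abs(diff(means))
    j <- which.min(dm)
    if (dm[j] < thr) {
      starts <- starts[-(j + 1L)]
      next
    }
    break
  }

  ends <- c(starts[-1L] - 1L, n)
  segs <- data.frame(
    start = starts, end = ends + 1L, n_samples = ends - starts + 1L,
    dwell_s = (ends - starts + 1L) / trace$sample_rate_Hz,
    mean_pA = segment_means(cs, starts, n))
  structure(
    list(segments = segs, trace_id = trace$trace_id,
         voltage_mV = trace$protocol$v_start_mV,
         sample_rate_Hz = trace$sample_rate_Hz, n_samples = n,
         noise_sd_pA = sigma, params = params),
    class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf(
    "idealized_trace '%s' (%+g mV): %d segment(s), noise %.3g pA\n",
    x$trace_id, x$voltage_mV, nrow(x$segments), x$noise_sd_pA))
  invisible(x)
}

#' Piecewise-constant reconstruction of an idealization
#'
#' Rebuilds the sample-by-sample idealized current (each sample replaced by
#' its segment mean), e.g. for overlay plots or idempotence checks.
#'
#' @param ideal an [idealize_trace()] result.
#' @return Numeric vector of length `n_samples`.
#' @export
reconstruct_current <- function(ideal) {
  if (!inherits(ideal, "idealized_trace"))
    stop_invalid("'ideal' must be an idealized_trace")
  rep(ideal$segments$mean_pA, ideal$segments$n_samples)
}

#' Extract gating events from an idealized trace
#'
#' One event per adjacent segment pair: the signed amplitude is the
#' difference of segment means, converted to conductance by
#' `|delta_I| * 1000 / |V - E_rev_assumed|` (pS). Events at
#' `|V - E_rev_assumed| < 10` mV are dropped because the conversion is
#' ill-conditioned there.
#'
#' @param ideal the [idealize_trace()] result for `trace`.
#' @param trace the source [current_trace()].
#' @param params the [idealization_params()] (supplies `e_rev_assumed_mV`).
#' @return A `data.frame` of class `"gating_events"` with columns `time_s`,
#'   `voltage_mV`, `delta_I_pA`, `conductance_pS`, `polarity`
#'   (`"negative"`/`"positive"` from the sign of V), `dwell_pre_s`,
#'   `dwell_post_s`.
#' @export
extract_gating_events <- function(ideal, trace,
                                  params = idealization_params()) {
  if (!inherits(ideal, "idealized_trace"))
    stop_invalid("'ideal' must be an idealized_trace")
  if (!inherits(trace, "current_trace"))
    stop_invalid("'trace' must be a current_trace")
  if (!identical(ideal$trace_id, trace$trace_id) ||
      ideal$n_samples != length(trace$current_pA))
    stop_invalid("idealization does not match the supplied trace")
  segs <- ideal$segments
  empty <- data.frame(time_s = numeric(0), voltage_mV = numeric(0),
                      delta_I_pA = numeric(0), conductance_pS = numeric(0),
                      polarity = character(0), dwell_pre_s = numeric(0),
                      dwell_post_s = numeric(0))
  if (nrow(segs) < 2L) {
    class(empty) <- c("gating_events", "data.frame")
    return(empty)
  }
  b <- segs$start[-1L]
  v <- trace$voltage_mV[b]
  denom <- abs(v - params$e_rev_assumed_mV)
  keep <- denom >= 10
  out <- data.frame(
    time_s = trace$time_s[b],
    voltage_mV = v,
    delta_I_pA = diff(segs$mean_pA),
    conductance_pS = abs(diff(segs$mean_pA)) * 1000 / denom,
    polarity = ifelse(v >= 0, "positive", "negative"),
    dwell_pre_s = segs$dwell_s[-nrow(segs)],
    dwell_post_s = segs$dwell_s[-1L])[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gating_events", "data.frame")
  attr(out, "trace_id") <- trace$trace_id
  out
}
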