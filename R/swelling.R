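# Liposome swelling-assay (OD500) simulation and summary.
#
# Osmotic shock with 300 mM KCl shrinks vesicles, dropping the optical
# density at 500 nm; ion influx through a reconstituted channel then lets
# the vesicles re-swell, so OD recovers toward baseline. Protein-free (or
# channel-free) liposomes stay at the dropped level. The simulator models
# this as an instantaneous drop at the salt-addition time followed by
# first-order relaxation back to baseline, plus Gaussian measurement noise;
# the summary reduces a measured time course to baseline, post-salt minimum
# and recovery slope, and calls channel presence from the slope.

#' Parameters of a simulated swelling-assay time course
#'
#' @param od_baseline pre-salt optical density at 500 nm (default 0.1, the
#'   usual assay starting density).
#' @param drop_fraction fraction of the baseline lost at salt addition,
#'   in `[0, 1)`.
#' @param recovery_rate_per_min first-order rate (1/min) of OD recovery
#'   toward baseline; 0 for channel-free liposomes.
#' @param noise_sd_od Gaussian measurement-noise SD (OD units). The default
#'   0.002 is 2% of the default baseline, inside the 1.5-3% replicate-SD
#'   band typical of the assay.
#' @param salt_time_min time of KCl addition (min).
#' @param duration_min total duration (min).
#' @param sample_interval_min sampling interval (min); OD is read once per
#'   minute by default.
#' @param seed integer RNG seed.
#' @param label identifier for the simulated trace.
#' @return An object of class `"swelling_params"`.
#' @export
swelling_params <- function(od_baseline = 0.1, drop_fraction = 0.2,
                            recovery_rate_per_min = 0.02,
                            noise_sd_od = 0.002, salt_time_min = 5,
                            duration_min = 60, sample_interval_min = 1,
                            seed = 1L, label = "swelling") {
  check_scalar_number(od_baseline, "od_baseline", positive = TRUE)
  check_scalar_number(drop_fraction, "drop_fraction")
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop_invalid("'drop_fraction' must be in [0, 1)")
  check_scalar_number(recovery_rate_per_min, "recovery_rate_per_min")
  if (recovery_rate_per_min < 0)
    stop_invalid("'recovery_rate_per_min' must be >= 0")
  check_scalar_number(noise_sd_od, "noise_sd_od")
  if (noise_sd_od < 0) stop_invalid("'noise_sd_od' must be >= 0")
  check_scalar_number(salt_time_min, "salt_time_min")
  check_scalar_number(duration_min, "duration_min", positive = TRUE)
  check_scalar_number(sample_interval_min, "sample_interval_min",
                      positive = TRUE)
  if (salt_time_min < 0 || salt_time_min > duration_min)
    stop_invalid("'salt_time_min' must lie within [0, duration_min]")
  structure(list(od_baseline = od_baseline, drop_fraction = drop_fraction,
                 recovery_rate_per_min = recovery_rate_per_min,
                 noise_sd_od = noise_sd_od, salt_time_min = salt_time_min,
                 duration_min = duration_min,
                 sample_interval_min = sample_interval_min,
                 seed = as.integer(seed), label = as.character(label)),
            class = "swelling_params")
}

#' Swelling-assay time course
#'
#' @param time_min sample times (min), strictly increasing.
#' @param od500 optical density at 500 nm, >= 0.
#' @param salt_time_min time of KCl addition (min), within the time range.
#' @param label identifier.
#' @return An object of class `"swelling_trace"`.
#' @export
swelling_trace <- function(time_min, od500, salt_time_min, label = "trace") {
  time_min <- as.numeric(time_min)
  od500 <- as.numeric(od500)
  if (length(time_min) != length(od500))
    stop_invalid("'time_min' and 'od500' must have equal lengths")
  if (length(time_min) < 2L)
    stop_invalid("swelling trace needs at least 2 samples")
  if (any(!is.finite(time_min)) || any(!is.finite(od500)))
    stop_invalid("swelling trace values must be finite")
  if (any(diff(time_min) <= 0))
    stop_invalid("'time_min' must be strictly increasing")
  if (any(od500 < 0)) stop_invalid("'od500' must be >= 0")
  check_scalar_number(salt_time_min, "salt_time_min")
  if (salt_time_min < time_min[1L] || salt_time_min > time_min[length(time_min)])
    stop_invalid("'salt_time_min' outside the sampled time range")
  structure(list(time_min = time_min, od500 = od500,
                 salt_time_min = as.numeric(salt_time_min),
                 label = as.character(label)),
            class = "swelling_trace")
}

#' @export
plot.swelling_trace <- function(x, ...) {
  plot(x$time_min, x$od500, type = "l", xlab = "time (min)",
       ylab = expression(OD[500]), main = x$label, ...)
  abline(v = x$salt_time_min, lty = 3)
  invisible(x)
}

#' Simulate a swelling-assay time course
#'
#' `OD(t) = baseline` before salt addition; from `salt_time_min` on,
#' `OD(t) = baseline * (1 - drop_fraction * exp(-recovery_rate * (t - t_salt)))`
#' (instantaneous osmotic drop followed by first-order recovery toward the
#' baseline), plus Gaussian noise. With `recovery_rate_per_min = 0` the OD
#' stays at the dropped level, the channel-free behaviour. Deterministic
#' given the seed.
#'
#' @param params a [swelling_params()].
#' @return A [swelling_trace()].
#' @export
simulate_swelling <- function(params) {
  if (!inherits(params, "swelling_params"))
    stop_invalid("'params' must be a swelling_params")
  t <- seq(0, params$duration_min, by = params$sample_interval_min)
  od <- rep(params$od_baseline, length(t))
  post <- t >= params$salt_time_min
  od[post] <- params$od_baseline *
    (1 - params$drop_fraction *
       exp(-params$recovery_rate_per_min * (t[post] - params$salt_time_min)))
  noise <- with_seed(params$seed, rnorm(length(t), 0, params$noise_sd_od))
  swelling_trace(t, pmax(od + noise, 0), params$salt_time_min, params$label)
}

#' Summarize a swelling-assay time course and call channel presence
#'
#' Baseline is the mean OD before salt addition; the post-salt minimum marks
#' the shrunken state; the recovery slope is the least-squares slope of OD
#' versus time from the minimum to the end of the record. The trace is called
#' `channel_positive` iff the recovery slope exceeds `slope_threshold_per_min`
#' (default: 3 standard errors of the fitted slope, a signal-significance
#' rule).
#'
#' @param trace a [swelling_trace()] with >= 3 pre-salt and >= 5 post-salt
#'   samples.
#' @param slope_threshold_per_min positive-call threshold on the recovery
#'   slope (OD/min); `NULL` for the default 3-SE rule.
#' @return An object of class `"swelling_summary"` with fields
#'   `od_baseline`, `od_min`, `recovery_slope_per_min`, `slope_se_per_min`,
#'   `threshold_per_min`, `call`.
#' @export
summarize_swelling <- function(trace, slope_threshold_per_min = NULL) {
  if (!inherits(trace, "swelling_trace"))
    stop_invalid("'trace' must be a swelling_trace")
  pre <- trace$time_min < trace$salt_time_min
  post <- !pre
  if (sum(pre) < 3L)
    stop_invalid("need at least 3 pre-salt samples (got ", sum(pre), ")")
  if (sum(post) < 5L)
    stop_invalid("need at least 5 post-salt samples (got ", sum(post), ")")
  od_baseline <- mean(trace$od500[pre])
  t_post <- trace$time_min[post]
  od_post <- trace$od500[post]
  i_min <- which.min(od_post)
  od_min <- od_post[i_min]
  t_fit <- t_post[i_min:length(t_post)]
  od_fit <- od_post[i_min:length(od_post)]
  if (length(t_fit) >= 3L) {
    fit <- lm(od_fit ~ t_fit)
    slope <- unname(coef(fit)[2L])
    se <- suppressWarnings(summary(fit))$coefficients[2L, 2L]
  } else {
    # minimum at (or next to) the end of the record: no recovery window
    slope <- 0
    se <- Inf
  }
  threshold <- slope_threshold_per_min %||% (3 * se)
  call <- if (is.finite(slope) && slope > threshold) "channel_positive"
          else "channel_negative"
  structure(list(od_baseline = od_baseline, od_min = od_min,
                 recovery_slope_per_min = slope, slope_se_per_min = se,
                 threshold_per_min = threshold, call = call,
                 label = trace$label),
            class = "swelling_summary")
}

#' @export
print.swelling_summary <- function(x, ...) {
  cat(sprintf(
    "swelling_summary '%s': baseline %.4f, min %.4f, slope %.2e OD/min -> %s\n",
    x$label, x$od_baseline, x$od_min, x$recovery_slope_per_min, x$call))
  invisible(x)
}
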