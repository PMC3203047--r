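# Continuous-time Markov single-channel simulator.
#
# A channel is a set of conductance levels (fully open first) with a matrix
# of transition rates between them. Gating is sampled exactly (Gillespie):
# the dwell in level i is exponential with rate equal to the sum of outgoing
# rates, and the next level is drawn with probability proportional to its
# rate. Rendering converts a latent state path into a sampled current trace
# under a step or ramp protocol, with rectification modelled as a
# polarity-dependent slope conductance per level and the reversal potential
# set by the GHK voltage equation for the buffer and the model's
# permeability ratio.

#' Conductance level of a channel model
#'
#' One gating level with polarity-dependent slope conductance: `g_neg_pS`
#' applies when the driving potential is below the reversal potential,
#' `g_pos_pS` at or above it. Unequal values make the level rectifying.
#'
#' @param level_id identifier string.
#' @param g_neg_pS slope conductance for V < E_rev (pS), >= 0.
#' @param g_pos_pS slope conductance for V >= E_rev (pS); defaults to
#'   `g_neg_pS` (ohmic level).
#' @return An object of class `"conductance_level"`.
#' @export
conductance_level <- function(level_id, g_neg_pS, g_pos_pS = g_neg_pS) {
  check_scalar_number(g_neg_pS, "g_neg_pS")
  check_scalar_number(g_pos_pS, "g_pos_pS")
  if (g_neg_pS < 0 || g_pos_pS < 0)
    stop_invalid("conductances must be >= 0")
  structure(list(level_id = as.character(level_id),
                 g_neg_pS = as.numeric(g_neg_pS),
                 g_pos_pS = as.numeric(g_pos_pS)),
            class = "conductance_level")
}

#' Markov channel-gating model
#'
#' Defines the gating levels (the first is the fully open state), the matrix
#' of transition rates between them, the K+:Cl- permeability ratio that fixes
#' the reversal potential under an ionic gradient, and the standard deviation
#' of the white Gaussian recording noise added when rendering.
#'
#' @param levels list of [conductance_level()] objects (a single level may be
#'   passed unwrapped); `levels[[1]]` is the fully open state.
#' @param rates_per_s square numeric matrix of transition rates (1/s);
#'   `rates_per_s[i, j]` is the rate from level i to level j. Off-diagonal
#'   entries must be >= 0; the diagonal is ignored. Defaults to all-zero
#'   rates (a channel frozen in its initial level).
#' @param permeability_ratio P_K/P_Cl, > 0.
#' @param noise_sd_pA Gaussian recording-noise standard deviation (pA), >= 0.
#' @return An object of class `"channel_model"`.
#' @seealso [tic20_channel_model()] for the packaged example model.
#' @export
channel_model <- function(levels, rates_per_s = NULL, permeability_ratio = 1,
                          noise_sd_pA = 0) {
  if (inherits(levels, "conductance_level")) levels <- list(levels)
  if (!length(levels) || !all(vapply(levels, inherits, logical(1),
                                     "conductance_level")))
    stop_invalid("'levels' must be a non-empty list of conductance_level")
  k <- length(levels)
  if (is.null(rates_per_s)) rates_per_s <- matrix(0, k, k)
  rates_per_s <- as.matrix(rates_per_s)
  if (nrow(rates_per_s) != k || ncol(rates_per_s) != k)
    stop_invalid("'rates_per_s' must be a ", k, "x", k, " matrix")
  off <- rates_per_s[row(rates_per_s) != col(rates_per_s)]
  if (any(!is.finite(off)) || any(off < 0))
    stop_invalid("off-diagonal transition rates must be finite and >= 0")
  check_scalar_number(permeability_ratio, "permeability_ratio", positive = TRUE)
  check_scalar_number(noise_sd_pA, "noise_sd_pA")
  if (noise_sd_pA < 0) stop_invalid("'noise_sd_pA' must be >= 0")
  structure(
    list(levels = levels, rates_per_s = rates_per_s,
         permeability_ratio = as.numeric(permeability_ratio),
         noise_sd_pA = as.numeric(noise_sd_pA)),
    class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("channel_model: %d level(s), P_K/P_Cl = %g, noise %g pA\n",
              length(x$levels), x$permeability_ratio, x$noise_sd_pA))
  for (lv in x$levels)
    cat(sprintf("  %-12s g = %g / %g pS (V<E_rev / V>=E_rev)\n",
                lv$level_id, lv$g_neg_pS, lv$g_pos_pS))
  invisible(x)
}

level_conductances <- function(model) {
  cbind(g_neg = vapply(model$levels, `[[`, numeric(1), "g_neg_pS"),
        g_pos = vapply(model$levels, `[[`, numeric(1), "g_pos_pS"))
}

#' Example Tic20-like channel model
#'
#' A three-level model emulating the reconstituted Tic20 channel: a mostly
#' occupied fully open level with rectifying total conductance (1260 pS at
#' negative, 1010 pS at positive potentials), plus two sub-conductance levels
#' reached by gating steps of 150 and 350 pS, one on each side of the
#' conductance-class boundaries (220 pS at negative, 180 pS at positive
#' potentials). With the default rates the channel spends ~91% of the time
#' fully open and leaves it at 4 events/s; substate dwells average 25 ms.
#' The permeability ratio of 6.5 reverses at +37 mV under a 250/20 mM KCl
#' gradient at 293.15 K.
#'
#' @param noise_sd_pA recording-noise SD (pA).
#' @param permeability_ratio P_K/P_Cl.
#' @return A [channel_model()].
#' @export
tic20_channel_model <- function(noise_sd_pA = 2, permeability_ratio = 6.5) {
  levels <- list(
    conductance_level("open",   1260, 1010),
    conductance_level("sub150", 1110,  860),
    conductance_level("sub350",  910,  660))
  rates <- matrix(c(0,  2, 2,
                    40, 0, 0,
                    40, 0, 0), nrow = 3, byrow = TRUE)
  channel_model(levels, rates, permeability_ratio = permeability_ratio,
                noise_sd_pA = noise_sd_pA)
}

#' Stationary distribution of a gating rate matrix
#'
#' Solves pi Q = 0, sum(pi) = 1 for the continuous-time generator built from
#' the off-diagonal transition rates. Used to predict long-run level
#' occupancies of [sample_state_path()] and mean rendered currents.
#'
#' @param rates_per_s square rate matrix (1/s), diagonal ignored.
#' @return Numeric vector of stationary occupancy probabilities.
#' @export
stationary_distribution <- function(rates_per_s) {
  q <- as.matrix(rates_per_s)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  n <- nrow(q)
  a <- rbind(t(q), rep(1, n))
  p <- qr.solve(a, c(rep(0, n), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Sample a gating state path (exact stochastic simulation)
#'
#' Gillespie sampling of the continuous-time Markov gating model: dwell times
#' are exponential with the level's total exit rate and the successor level
#' is drawn proportionally to its rate. A level with no outgoing rate is
#' absorbing and yields a single final segment. Deterministic given
#' `(model, duration_s, seed)`.
#'
#' @param model a [channel_model()].
#' @param duration_s path duration (s), > 0.
#' @param seed integer RNG seed.
#' @param init_level index of the starting level (default 1, fully open).
#' @return A `data.frame` of class `"state_path"` with columns `level`
#'   (index), `level_id`, `start_s`, `end_s`; segments are contiguous and
#'   cover `[0, duration_s]`. The duration and seed are kept as attributes.
#' @export
sample_state_path <- function(model, duration_s, seed, init_level = 1L) {
  if (!inherits(model, "channel_model"))
    stop_invalid("'model' must be a channel_model")
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  k <- length(model$levels)
  if (init_level < 1L || init_level > k)
    stop_invalid("'init_level' out of range")
  rates <- model$rates_per_s
  diag(rates) <- 0
  exit_rate <- rowSums(rates)
  cum_prob <- lapply(seq_len(k), function(i) {
    if (exit_rate[i] > 0) cumsum(rates[i, ] / exit_rate[i]) else NULL
  })

  cap <- 1024L
  lev <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  m <- 0L
  with_seed(seed, {
    s <- as.integer(init_level)
    t <- 0
    repeat {
      if (m == cap) {
        cap <- cap * 2L
        length(lev) <- cap; length(t0) <- cap; length(t1) <- cap
      }
      m <- m + 1L
      lev[m] <- s; t0[m] <- t
      if (exit_rate[s] == 0) {          # absorbing level
        t1[m] <- duration_s
        break
      }
      t_next <- t + rexp(1L, exit_rate[s])
      if (t_next >= duration_s) {
        t1[m] <- duration_s
        break
      }
      t1[m] <- t_next
      t <- t_next
      s <- findInterval(runif(1L), cum_prob[[s]]) + 1L
    }
  })
  ids <- vapply(model$levels, `[[`, character(1), "level_id")
  out <- data.frame(level = lev[seq_len(m)], level_id = ids[lev[seq_len(m)]],
                    start_s = t0[seq_len(m)], end_s = t1[seq_len(m)])
  class(out) <- c("state_path", "data.frame")
  attr(out, "duration_s") <- duration_s
  attr(out, "seed") <- seed
  out
}

#' GHK reversal potential for a single binary salt
#'
#' Goldman-Hodgkin-Katz voltage equation for KCl with cation:anion
#' permeability ratio `r = P_K/P_Cl`:
#' `E_rev = (RT/F) * ln((r*C_cis + C_trans) / (r*C_trans + C_cis))`, in mV,
#' with the cis-relative sign convention of [current_trace()]. Symmetric
#' buffers and `r = 1` give exactly 0. Strictly increasing in `r` and bounded
#' above by the K+ Nernst potential.
#'
#' @param permeability_ratio P_K/P_Cl, > 0.
#' @param buffer a [buffer_condition()].
#' @return Reversal potential (mV).
#' @seealso [ghk_permeability_ratio()] for the inverse,
#'   [nernst_potential_mV()] for the limiting case.
#' @export
ghk_reversal_mV <- function(permeability_ratio, buffer) {
  check_scalar_number(permeability_ratio, "permeability_ratio", positive = TRUE)
  if (!inherits(buffer, "buffer_condition"))
    stop_invalid("'buffer' must be a buffer_condition")
  r <- permeability_ratio
  cc <- buffer$kcl_cis_mM
  ct <- buffer$kcl_trans_mM
  1000 * PHYS_R * buffer$temperature_K / PHYS_F *
    log((r * cc + ct) / (r * ct + cc))
}

#' Render a state path into a sampled current trace
#'
#' Per sample, `I_pA = g_level(polarity) * (V - E_rev)/1000 + N(0, noise_sd)`
#' with `E_rev` from [ghk_reversal_mV()] for the model's permeability ratio
#' and the buffer, and the polarity (which of the level's two slope
#' conductances applies) chosen by the sign of `V - E_rev`. Deterministic
#' given the seed; the noise stream is independent of the gating stream.
#'
#' @param path a `state_path` covering at least the protocol duration.
#' @param model the [channel_model()] that generated `path`.
#' @param protocol a [voltage_protocol()].
#' @param buffer a [buffer_condition()].
#' @param sample_rate_Hz sampling rate (Hz).
#' @param seed integer seed for the noise stream.
#' @param trace_id identifier; default derives from protocol and seed.
#' @return A [current_trace()] with full metadata embedded.
#' @export
render_current <- function(path, model, protocol, buffer, sample_rate_Hz,
                           seed, trace_id = NULL) {
  if (!inherits(path, "state_path")) stop_invalid("'path' must be a state_path")
  if (!inherits(model, "channel_model"))
    stop_invalid("'model' must be a channel_model")
  if (!inherits(protocol, "voltage_protocol"))
    stop_invalid("'protocol' must be a voltage_protocol")
  check_scalar_number(sample_rate_Hz, "sample_rate_Hz", positive = TRUE)
  dur <- protocol$duration_s
  if (max(path$end_s) < dur)
    stop_invalid("state path shorter than the protocol duration")
  n <- as.integer(round(dur * sample_rate_Hz))
  if (n < 1L) stop_invalid("protocol shorter than one sample period")
  t <- (seq_len(n) - 1L) / sample_rate_Hz
  v <- if (protocol$kind == "step") {
    rep(protocol$v_start_mV, n)
  } else {
    protocol$v_start_mV + t / dur * (protocol$v_end_mV - protocol$v_start_mV)
  }
  min_dwell <- min(path$end_s - path$start_s)
  if (min_dwell < 1 / sample_rate_Hz)
    warning(sprintf(
      "sample rate %g Hz cannot resolve the shortest dwell (%.3g s)",
      sample_rate_Hz, min_dwell))
  e_rev <- ghk_reversal_mV(model$permeability_ratio, buffer)
  seg <- findInterval(t, path$start_s)
  lev <- path$level[seg]
  g <- level_conductances(model)
  g_samp <- ifelse(v >= e_rev, g[lev, "g_pos"], g[lev, "g_neg"])
  i_pa <- g_samp * (v - e_rev) / 1000
  noise <- with_seed(seed, rnorm(n, mean = 0, sd = model$noise_sd_pA))
  current_trace(
    time_s = t, current_pA = i_pa + noise, voltage_mV = v,
    sample_rate_Hz = sample_rate_Hz, buffer = buffer, protocol = protocol,
    trace_id = trace_id %||% sprintf("sim-%s-%d", protocol$kind, seed))
}
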