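# Reversal-potential extraction from voltage ramps and ion-selectivity
# computations (GHK inversion, Nernst reference).

#' Reversal potential pooled over voltage ramps
#'
#' For each asymmetric-buffer ramp recording, the current is smoothed with a
#' centred moving average spanning `smooth_window_mV` of the ramp, the zero
#' crossings of current versus voltage are located by linear interpolation,
#' and the median crossing is taken if there are several. Ramps without a
#' crossing are excluded with a warning; the estimate pools the remaining
#' ramps (mean and standard error).
#'
#' @param ramps a [current_trace()] or list of them; every trace must use a
#'   ramp protocol and an asymmetric buffer.
#' @param smooth_window_mV smoothing span (mV, default 5).
#' @return An object of class `"reversal_estimate"`: `e_rev_mV`, `sem_mV`,
#'   `n_ramps`, `per_ramp_mV`.
#' @export
find_reversal_potential <- function(ramps, smooth_window_mV = 5) {
  if (inherits(ramps, "current_trace")) ramps <- list(ramps)
  if (!length(ramps) || !all(vapply(ramps, inherits, logical(1),
                                    "current_trace")))
    stop_invalid("'ramps' must be a list of current_trace objects")
  check_scalar_number(smooth_window_mV, "smooth_window_mV", positive = TRUE)
  per_ramp <- numeric(0)
  for (tr in ramps) {
    if (tr$protocol$kind != "ramp")
      stop_invalid("trace '", tr$trace_id, "' does not use a ramp protocol")
    if (is_symmetric_buffer(tr$buffer))
      stop_invalid("trace '", tr$trace_id,
                   "' was recorded under a symmetric buffer; ",
                   "reversal extraction needs an ionic gradient")
    v <- tr$voltage_mV
    span <- abs(tr$protocol$v_end_mV - tr$protocol$v_start_mV)
    w <- max(1L, round(smooth_window_mV / span * length(v)))
    i_s <- moving_average(tr$current_pA, w)
    s <- sign(i_s)
    cross <- which(s[-length(s)] * s[-1L] < 0)
    exact <- which(s == 0)
    xs <- c(v[exact],
            v[cross] - i_s[cross] * (v[cross + 1L] - v[cross]) /
              (i_s[cross + 1L] - i_s[cross]))
    if (!length(xs)) {
      warning("trace '", tr$trace_id,
              "' has no zero crossing in range; excluded")
      next
    }
    per_ramp <- c(per_ramp, median(xs))
  }
  if (!length(per_ramp))
    stop_invalid("no ramp yielded a zero crossing; cannot estimate reversal")
  structure(list(
    e_rev_mV = mean(per_ramp),
    sem_mV = if (length(per_ramp) > 1L) sd(per_ramp) / sqrt(length(per_ramp))
             else 0,
    n_ramps = length(per_ramp),
    per_ramp_mV = per_ramp),
    class = "reversal_estimate")
}

#' @export
print.reversal_estimate <- function(x, ...) {
  cat(sprintf("reversal_estimate: %.1f +/- %.1f mV (n = %d ramps)\n",
              x$e_rev_mV, x$sem_mV, x$n_ramps))
  invisible(x)
}

#' Permeability ratio from a measured reversal potential (GHK inversion)
#'
#' Closed-form inverse of [ghk_reversal_mV()] for a single binary salt:
#' with `xi = exp(E_rev * F / (R * T))`,
#' `P_K/P_Cl = (xi * C_cis - C_trans) / (C_cis - xi * C_trans)`. The
#' measured reversal must lie strictly inside the Nernst bounds of the
#' gradient (equivalently `xi` strictly between `C_trans/C_cis` and
#' `C_cis/C_trans`), outside of which no finite permeability ratio exists.
#'
#' @param e_rev_mV measured reversal potential (mV), cis-relative sign
#'   convention.
#' @param buffer an asymmetric [buffer_condition()].
#' @return An object of class `"selectivity_result"`:
#'   `permeability_ratio` (P_K/P_Cl), `e_rev_used_mV`, `buffer`.
#' @export
ghk_permeability_ratio <- function(e_rev_mV, buffer) {
  check_scalar_number(e_rev_mV, "e_rev_mV")
  if (!inherits(buffer, "buffer_condition"))
    stop_invalid("'buffer' must be a buffer_condition")
  if (is_symmetric_buffer(buffer))
    stop_invalid("buffer is symmetric; the permeability ratio is ",
                 "unidentifiable without an ionic gradient")
  cc <- buffer$kcl_cis_mM
  ct <- buffer$kcl_trans_mM
  xi <- exp(e_rev_mV / 1000 * PHYS_F / (PHYS_R * buffer$temperature_K))
  lo <- min(ct / cc, cc / ct)
  hi <- max(ct / cc, cc / ct)
  if (xi <= lo || xi >= hi) {
    nb <- nernst_potential_mV(cc, ct, valence = 1,
                              temperature_K = buffer$temperature_K)
    stop_invalid(sprintf(
      paste0("e_rev_mV = %.3g mV lies outside the Nernst bounds ",
             "(+/- %.3g mV for this gradient); no finite permeability ",
             "ratio exists"), e_rev_mV, abs(nb)))
  }
  structure(list(permeability_ratio = (xi * cc - ct) / (cc - xi * ct),
                 e_rev_used_mV = e_rev_mV, buffer = buffer),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf(
    "selectivity_result: P_K/P_Cl = %.2f at E_rev = %.1f mV (KCl %g/%g mM)\n",
    x$permeability_ratio, x$e_rev_used_mV, x$buffer$kcl_cis_mM,
    x$buffer$kcl_trans_mM))
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' `(RT / zF) * ln(C_cis / C_trans)` in mV: the reversal potential of a
#' channel perfectly selective for an ion of valence `z`, and the limiting
#' value of [ghk_reversal_mV()] as the permeability ratio grows without
#' bound.
#'
#' @param c_cis_mM,c_trans_mM ion concentrations (mM), > 0.
#' @param valence signed ion valence (non-zero integer; +1 for K+).
#' @param temperature_K absolute temperature (K).
#' @return Potential (mV).
#' @export
nernst_potential_mV <- function(c_cis_mM, c_trans_mM, valence = 1,
                                temperature_K = 293.15) {
  check_scalar_number(c_cis_mM, "c_cis_mM", positive = TRUE)
  check_scalar_number(c_trans_mM, "c_trans_mM", positive = TRUE)
  check_scalar_number(valence, "valence")
  if (valence == 0) stop_invalid("'valence' must be non-zero")
  check_scalar_number(temperature_K, "temperature_K", positive = TRUE)
  1000 * PHYS_R * temperature_K / (valence * PHYS_F) *
    log(c_cis_mM / c_trans_mM)
}
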