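# Conductance-class assignment, histograms, per-class I-V fits and the
# fully-open (total) conductance per polarity.

#' Conductance-class definitions
#'
#' Polarity-specific thresholds splitting gating events into class I (below)
#' and class II (at or above the threshold). Defaults are 220 pS at negative
#' and 180 pS at positive potentials.
#'
#' @param threshold_neg_pS,threshold_pos_pS class I/II boundary (pS) at
#'   negative / positive potentials.
#' @return A `data.frame` with columns `polarity` and `threshold_pS`.
#' @export
class_defs <- function(threshold_neg_pS = 220, threshold_pos_pS = 180) {
  check_scalar_number(threshold_neg_pS, "threshold_neg_pS", positive = TRUE)
  check_scalar_number(threshold_pos_pS, "threshold_pos_pS", positive = TRUE)
  data.frame(polarity = c("negative", "positive"),
             threshold_pS = c(threshold_neg_pS, threshold_pos_pS))
}

#' Assign conductance classes to gating events
#'
#' Class II iff `conductance_pS >= threshold` for the event's polarity,
#' class I otherwise; every event gets exactly one class.
#'
#' @param events a `gating_events` data frame (see
#'   [extract_gating_events()]).
#' @param defs class definitions from [class_defs()]; each event polarity
#'   must be covered by exactly one row.
#' @return `events` with an added `class_id` column (`"I"`/`"II"`).
#' @export
assign_classes <- function(events, defs = class_defs()) {
  if (!all(c("conductance_pS", "polarity") %in% names(events)))
    stop_invalid("'events' must have conductance_pS and polarity columns")
  if (anyDuplicated(defs$polarity))
    stop_invalid("duplicate polarity in class definitions")
  idx <- match(events$polarity, defs$polarity)
  if (anyNA(idx) && nrow(events))
    stop_invalid("no class definition for polarity '",
                 events$polarity[which(is.na(idx))[1L]], "'")
  events$class_id <- ifelse(events$conductance_pS >= defs$threshold_pS[idx],
                            "II", "I")
  if (!nrow(events)) events$class_id <- character(0)
  events
}

#' Conductance histogram of gating events at one polarity
#'
#' Left-closed right-open bins of width `bin_width_pS` from 0 up past the
#' largest event conductance; counts conserve the number of contributing
#' events. An empty event list yields an empty (zero-bin) histogram.
#'
#' @param events a `gating_events` data frame.
#' @param polarity `"negative"` or `"positive"`.
#' @param bin_width_pS bin width (pS); the default 25 pS matches the
#'   smallest gating events typically resolved.
#' @return An object of class `"conductance_histogram"` with fields
#'   `polarity`, `bin_edges_pS`, `counts`, `n_events`.
#' @export
conductance_histogram <- function(events, polarity = c("negative", "positive"),
                                  bin_width_pS = 25) {
  polarity <- match.arg(polarity)
  check_scalar_number(bin_width_pS, "bin_width_pS", positive = TRUE)
  g <- events$conductance_pS[events$polarity == polarity]
  if (!length(g)) {
    return(structure(list(polarity = polarity, bin_edges_pS = numeric(0),
                          counts = integer(0), n_events = 0L),
                     class = "conductance_histogram"))
  }
  edges <- seq(0, bin_width_pS * (floor(max(g) / bin_width_pS) + 1L),
               by = bin_width_pS)
  counts <- graphics::hist(g, breaks = edges, right = FALSE,
                           plot = FALSE)$counts
  structure(list(polarity = polarity, bin_edges_pS = edges,
                 counts = as.integer(counts), n_events = length(g)),
            class = "conductance_histogram")
}

#' @export
print.conductance_histogram <- function(x, ...) {
  cat(sprintf("conductance_histogram (%s): %d events in %d bins\n",
              x$polarity, x$n_events, length(x$counts)))
  invisible(x)
}

#' @export
plot.conductance_histogram <- function(x, ...) {
  graphics::barplot(x$counts, width = diff(x$bin_edges_pS),
                    space = 0, xlab = "conductance (pS)", ylab = "events",
                    main = sprintf("%s polarity", x$polarity), ...)
  graphics::axis(1, at = pretty(x$bin_edges_pS))
  invisible(x)
}

#' Per-class linear current-voltage fits
#'
#' For each populated (polarity, class) group, an ordinary least-squares
#' line of the polarity-signed event amplitude against voltage; the slope,
#' converted to pS, is the class conductance. Groups with fewer than two
#' events are skipped with a warning.
#'
#' @param events a classified `gating_events` data frame (see
#'   [assign_classes()]).
#' @return A `data.frame` with one row per fitted class: `polarity`,
#'   `class_id`, `slope_conductance_pS`, `intercept_pA`, `n_events`,
#'   `r_squared`.
#' @export
fit_class_iv <- function(events) {
  if (!"class_id" %in% names(events))
    stop_invalid("'events' must be classified first (see assign_classes)")
  rows <- list()
  for (pol in c("negative", "positive")) {
    for (cl in c("I", "II")) {
      sub <- events[events$polarity == pol & events$class_id == cl, ,
                    drop = FALSE]
      if (!nrow(sub)) next
      if (nrow(sub) < 2L || length(unique(sub$voltage_mV)) < 2L) {
        warning(sprintf("class %s at %s polarity skipped (%d event(s))",
                        cl, pol, nrow(sub)))
        next
      }
      sgn <- if (pol == "positive") 1 else -1
      y <- sgn * abs(sub$delta_I_pA)
      fit <- lm(y ~ sub$voltage_mV)
      rows[[length(rows) + 1L]] <- data.frame(
        polarity = pol, class_id = cl,
        slope_conductance_pS = unname(coef(fit)[2L]) * 1000,
        intercept_pA = unname(coef(fit)[1L]),
        n_events = nrow(sub),
        r_squared = suppressWarnings(summary(fit)$r.squared))
    }
  }
  if (!length(rows))
    return(data.frame(polarity = character(0), class_id = character(0),
                      slope_conductance_pS = numeric(0),
                      intercept_pA = numeric(0), n_events = integer(0),
                      r_squared = numeric(0)))
  do.call(rbind, rows)
}

#' Fully open (total) conductance per polarity
#'
#' Identifies, in each idealized constant-voltage trace, the fully open
#' level (the segment with the largest absolute mean current, pooled with
#' all segments whose means lie within the detection threshold of it,
#' weighted by dwell) and regresses the open-level current on voltage
#' through the origin, separately for negative and positive voltages. The
#' through-origin form assumes a symmetric buffer (reversal at 0 mV).
#'
#' @param ideals list of [idealize_trace()] results over a multi-voltage
#'   step protocol, with at least 3 voltages of each polarity.
#' @return An object of class `"total_conductance"`: `g_neg_pS`, `g_pos_pS`,
#'   slope standard errors `se_neg_pS`, `se_pos_pS`, `n_voltages` per
#'   polarity, and the per-voltage open-level table `open_levels`.
#' @export
fully_open_conductance <- function(ideals) {
  if (inherits(ideals, "idealized_trace")) ideals <- list(ideals)
  if (!length(ideals) || !all(vapply(ideals, inherits, logical(1),
                                     "idealized_trace")))
    stop_invalid("'ideals' must be a list of idealized_trace objects")
  tab <- do.call(rbind, lapply(ideals, function(id) {
    segs <- id$segments
    i0 <- which.max(abs(segs$mean_pA))
    thr <- id$params$threshold_k * id$noise_sd_pA
    sel <- abs(segs$mean_pA - segs$mean_pA[i0]) <= thr
    data.frame(trace_id = id$trace_id, voltage_mV = id$voltage_mV,
               open_current_pA = weighted.mean(segs$mean_pA[sel],
                                               segs$dwell_s[sel]))
  }))
  fit_pol <- function(sub) {
    fit <- lm(open_current_pA ~ 0 + voltage_mV, data = sub)
    cf <- suppressWarnings(summary(fit))$coefficients
    c(g = unname(coef(fit)[1L]) * 1000, se = unname(cf[1L, 2L]) * 1000)
  }
  neg <- tab[tab$voltage_mV < 0, , drop = FALSE]
  pos <- tab[tab$voltage_mV > 0, , drop = FALSE]
  if (nrow(neg) < 3L || nrow(pos) < 3L)
    stop_invalid("need at least 3 voltages at each polarity (got ",
                 nrow(neg), " negative, ", nrow(pos), " positive)")
  fn <- fit_pol(neg)
  fp <- fit_pol(pos)
  structure(list(g_neg_pS = fn[["g"]], g_pos_pS = fp[["g"]],
                 se_neg_pS = fn[["se"]], se_pos_pS = fp[["se"]],
                 n_voltages = c(negative = nrow(neg), positive = nrow(pos)),
                 open_levels = tab),
            class = "total_conductance")
}

#' @export
print.total_conductance <- function(x, ...) {
  cat(sprintf(
    "total_conductance: %.0f +/- %.0f pS (negative), %.0f +/- %.0f pS (positive)\n",
    x$g_neg_pS, x$se_neg_pS, x$g_pos_pS, x$se_pos_pS))
  invisible(x)
}
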