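# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seeds: a Lehmer-style mix of (master, index) kept
# strictly inside the 32-bit signed range. Adding streams with a higher index
# never perturbs the seeds of earlier streams.
derive_seed <- function(master, index) {
  s <- as.numeric(master) %% 2147483647
  v <- (s * 48271 + as.numeric(index) * 8191 + 1) %% 2147483647
  as.integer(v)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid("'", name, "' must be a finite numeric scalar")
  if (positive && x <= 0)
    stop_invalid("'", name, "' must be > 0")
  invisible(x)
}

# Centered moving average with window w (odd or even); edges use the
# partial window so no samples are lost.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
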