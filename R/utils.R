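# Internal helpers: seeding, validation, small numerics.

#' Derive a reproducible sub-seed from a master seed and counters
#'
#' Counter-based seed derivation: the master seed plus any number of integer
#' counters (participant index, task index, trial index, fold index, ...) are
#' mixed through a multiplicative-congruential recurrence modulo 2^31 - 1.
#' The result does not depend on the order in which other sub-seeds were
#' drawn, so cohorts and experiments are reproducible independently of
#' generation order.
#'
#' @param seed integer master seed.
#' @param ... integer counters identifying the consumer of the sub-stream.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 3, 2) # stable across sessions
derive_seed <- function(seed, ...) {
  counters <- c(...)
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- as.double(seed %% m)
  # fold each counter in with distinct multipliers (both primitive roots mod m)
  for (k in counters) {
    s <- (s * 48271 + (as.double(k) + 1) * 16807) %% m
  }
  s <- (s * 48271 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` with a locally-set RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_kneeload <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "kneeload_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_kneeload(name, " must be a single finite number", class = "kneeload_config_error")
  }
  if (positive && x <= 0) {
    stop_kneeload(name, " must be > 0", class = "kneeload_config_error")
  }
  invisible(x)
}

# sample standard deviation, NA-safe for length-1 input (returns NA)
sample_sd <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}
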