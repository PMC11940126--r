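# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cbi <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cbiqus_error")
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cbi("`%s` must be a single finite number.", name)
  }
  if (strict_lower && x <= lower) {
    stop_cbi("`%s` must be > %g (got %g).", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_cbi("`%s` must be >= %g (got %g).", name, lower, x)
  }
  if (x > upper) stop_cbi("`%s` must be <= %g (got %g).", name, upper, x)
  invisible(x)
}

# amplitude ratio -> decibels and back
amp_to_db <- function(a, ref = 1) 20 * log10(a / ref)
db_to_amp <- function(db) 10^(db / 20)

# Plateau-safe local maxima of a numeric vector: returns indices i such that
# the value at i is strictly greater than the nearest differing values on
# both sides (for a plateau, the first index of the run is reported).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  is_max <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  first_idx[is_max]
}

# Fractional grid index for a round-trip time given a grid time base.
time_to_index <- function(t, grid) {
  (t - grid$window_start_time) * grid$sampling_rate + 1
}

index_to_time <- function(i, grid) {
  grid$window_start_time + (i - 1) / grid$sampling_rate
}
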