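# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; NULL seed means "use the current stream".
local_rng <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_helpdm <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_helpdm(sprintf("'%s' must lie in [0, 1]", what))
  }
  invisible(x)
}

assert_pos <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_helpdm(sprintf("'%s' must be > 0", what))
  }
  invisible(x)
}

assert_named_map <- function(x, keys, what) {
  if (length(x) != length(keys) || is.null(names(x)) ||
      !setequal(names(x), keys)) {
    stop_helpdm(sprintf("'%s' must have exactly the keys {%s}",
                        what, paste(keys, collapse = ", ")))
  }
  invisible(x)
}

# Largest-remainder apportionment of `n` items proportional to `weights`.
apportion <- function(n, weights) {
  if (n == 0L) return(rep(0L, length(weights)))
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Place `lengths` non-overlapping intervals uniformly at random inside
# [margin, total - margin); returns 0-based starts sorted left to right.
pack_intervals <- function(lengths, total, margin = 0) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  free <- total - 2 * margin - sum(lengths)
  if (free < 0) {
    stop_helpdm(sprintf(
      "infeasible packing: %d intervals totalling %d bp do not fit in %d bp",
      n, sum(lengths), total - 2 * margin))
  }
  offsets <- sort(floor(runif(n, 0, free + 1)))
  starts <- margin + offsets + c(0, cumsum(lengths[-n]))
  as.integer(starts)
}
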