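# Internal helpers: seeded draws that do not clobber the caller's RNG state,
# and small validation utilities shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a (cycle, channel) pair, shared across strategies
# so paired runs see common random numbers. Kept below 2^31 - 1.
stream_seed <- function(seed, cycle, channel) {
  base <- (as.double(seed) %% 1e6) * 1997L
  as.integer((base + cycle * 131L + channel * 7907L) %% 2147483629)
}

# n uniforms for one decision channel of one cycle.
channel_runif <- function(n, seed, cycle, channel) {
  with_seed(stream_seed(seed, cycle, channel), stats::runif(n))
}

is_prob <- function(x) is.numeric(x) & !is.na(x) & x >= 0 & x <= 1

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("%s must be a single non-missing number", name)
  }
  invisible(x)
}
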