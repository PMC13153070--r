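#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic components of the pipeline draw their seeds from a single
#' master seed through this function, so that partial re-runs (for example a
#' single replicate or a single subgroup) reproduce exactly the values they
#' had inside a full run.
#'
#' @param master integer master seed.
#' @param index non-negative integer identifying the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative congruential mix; modulus is prime and < 2^31
  m <- 2147483629
  as.integer(((abs(master) %% m) * 48271 + index * 9973 + 1) %% m)
}

# Deterministic integer hash of a character label, for per-label seeds.
label_seed <- function(label, master = 0L) {
  codes <- utf8ToInt(label)
  h <- 0
  for (i in seq_along(codes)) h <- (h * 131 + codes[i]) %% 2147483629
  seed_stream(master, h)
}

# Cascade (remainder-carrying) rounding: integer vector whose cumulative
# sums are the half-up-rounded cumulative sums of x, so interval totals
# are preserved and a lone 0.5 becomes 1 (base round() would drop it).
cascade_round <- function(x) {
  cs <- floor(cumsum(x) + 0.5)
  as.integer(diff(c(0, cs)))
}

# Right-continuous step-function evaluation of a (time, value) table at t.
eval_step <- function(time, value, t) {
  idx <- findInterval(t, time)
  out <- ifelse(idx == 0, value[1], value[pmax(idx, 1)])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
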