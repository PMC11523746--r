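# Internal seeding helpers. All user-facing randomness flows through a single
# integer seed; sub-seeds are derived deterministically so a whole scan or
# sweep is reproducible end-to-end from one value.

#' Derive a reproducible sub-seed from a master seed
#'
#' Linear-congruential mixing keeps the result a valid 32-bit R seed and
#' uncorrelated across consecutive indices.
#'
#' @param seed master integer seed.
#' @param i index of the consumer (window number, replicate number, ...).
#' @return An integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  # all intermediates stay < 2^53, exact in doubles
  as.integer(((abs(seed) %% 2147483647) * 69069 + i * 12345 + 1) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
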