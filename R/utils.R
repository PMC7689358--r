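# internal helpers shared across modules

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package funnel their `seed` argument
#' through this helper so the caller's RNG state is never disturbed.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

# population (divide-by-n) variance; heritability scaling uses realized
# in-sample variance so the realized h2 is tight at any n
pop_var <- function(x) mean((x - mean(x))^2)

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(master, stream, offset = 0L) {
  (as.integer(master) + 10000L * as.integer(stream) + as.integer(offset)) %% 2147483647L
}
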