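# Internal helpers: seed derivation and argument checking.

#' Derive a child seed from a master seed
#'
#' Counter-based scheme (multiplicative LCG step per index) so that every
#' stage, population and generation receives a reproducible seed that does not
#' shift when unrelated stages are added. All derived seeds stay in
#' `[0, 2^31 - 2]`.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param ... One or more integer counters (stage id, population index,
#'   generation index, ...).
#' @return An integer seed.
#' @examples
#' derive_seed(1, 3)
#' derive_seed(1, 3, 7)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  idx <- c(...)
  s <- abs(as.double(seed)) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(s)
}

# stop() with a consistent prefix-free message built from sprintf parts
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    .fail("'%s' must be a single number in [%g, %g]", name, lo, hi)
  }
  invisible(x)
}

.check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    .fail("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
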