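# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the package draw their randomness from a single
#' user-supplied integer seed; sub-stages use deterministic child seeds so
#' that, e.g., regenerating phenotypes does not disturb the genotype stream.
#' A fixed linear-congruential step keeps results below `2^31 - 1`.
#'
#' @param seed master seed (single integer).
#' @param k child index (single non-negative integer).
#' @return An integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L, k >= 0)
  as.integer(((abs(seed) %% 2147483647) * 48271 + 7919 * (k + 1)) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                       open_hi = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (open_lo) x > lo else x >= lo) &&
    all(if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("'%s' must lie in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  x
}

# Lower Cholesky factor of a (numerically) PSD matrix, with a small ridge
# so that Gram matrices with repeated rows remain factorizable.
chol_psd <- function(K, ridge = 1e-8) {
  t(chol(K + diag(ridge, nrow(K))))
}
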