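# Small shared helpers.

#' Derive a reproducible sub-stream seed
#'
#' A single pipeline seed deterministically spawns the seed of every stage and
#' every subject, so any stage can also be re-run standalone with the same
#' stream. Uses a Lehmer/Park-Miller step (modulus 2^31 - 1) whose products
#' stay exactly representable in doubles; results are always in
#' `[1, 2^31 - 2]`, safe for `set.seed()`.
#'
#' @param seed Integer base seed.
#' @param index Nonnegative integer stream index.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 5)
derive_seed <- function(seed, index) {
  stopifnot(length(seed) == 1, length(index) == 1, is.finite(seed),
            is.finite(index), index >= 0)
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  s <- (s + (index %% m) * 912367) %% m
  if (s == 0) s <- 1
  for (i in 1:3) s <- (48271 * s) %% m
  as.integer(s)
}

# round half away from zero, for one-decimal percentage reporting
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what = "input") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}
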