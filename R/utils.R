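#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half-to-even; printed percentages in genomics
#' results tables conventionally round halves up (26,428/49,846 -> 53.0).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded with halves away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count over a denominator, rounded half-up to 1 decimal
#'
#' @param numerator,denominator non-negative counts; `denominator > 0`.
#' @return percentage on the 0-100 scale with 1 decimal.
#' @export
overlap_fraction <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0)) stop("numerator must be >= 0")
  round_half_up(100 * numerator / denominator, 1)
}

#' Size of the union of two peak sets from their shared count
#'
#' Inclusion-exclusion on merged-region counts: `nA + nB - n_shared`.
#'
#' @param n_a,n_b set sizes; `n_shared` the shared-region count.
#' @return union count.
#' @export
union_count <- function(n_a, n_b, n_shared) {
  stopifnot(n_a >= 0, n_b >= 0, n_shared >= 0)
  out <- n_a + n_b - n_shared
  if (any(out < 0)) stop("shared count exceeds the union: inconsistent inputs")
  out
}

# local, deterministic RNG scope: every stochastic entry point takes an
# explicit seed and must not disturb the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
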