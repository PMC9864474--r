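# Minimal exact big-integer arithmetic: nonnegative integers as vectors of
# base-1e7 digits, least significant first, stored in doubles. Only the two
# operations the binomial coefficient needs are implemented: multiply by a
# machine integer and exact division by a machine integer. With base 1e7 and
# multipliers below ~9e8 every intermediate stays under 2^53, so all carries
# are exact.

.BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x == trunc(x))
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% .BIG_BASE)
    x <- x %/% .BIG_BASE
  }
  d
}

big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m < 9e8)
  prod <- a * m
  carry <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    v <- prod[i] + carry
    out[i] <- v %% .BIG_BASE
    carry <- v %/% .BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% .BIG_BASE)
    carry <- carry %/% .BIG_BASE
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

# Exact long division (most significant digit first); errors on a remainder,
# which cannot happen along the binomial recurrence.
big_div_small <- function(a, d) {
  stopifnot(d >= 1, d < 9e8)
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * .BIG_BASE + a[i]
    out[i] <- v %/% d
    rem <- v %% d
  }
  if (rem != 0) stop("big_div_small: inexact division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_string <- function(a) {
  n <- length(a)
  parts <- sprintf("%07.0f", a)
  parts[n] <- sprintf("%.0f", a[n])
  paste(rev(parts), collapse = "")
}

#' Exact search-space size of the subset-selection problem
#'
#' Number of distinct size-`n` subsets of a population of `N` items, the
#' binomial coefficient \eqn{\binom{N}{n}}, computed in exact arbitrary
#' precision. This is the number of candidate sets an exhaustive search must
#' score: already at N = 50000, n = 3 it exceeds 20 trillion, which is why the
#' greedy heuristic exists.
#'
#' @param N population size, a nonnegative integer.
#' @param n subset size, an integer in `[0, N]`.
#' @return An object of class `sds_bigint`. Use [as.character()] for the exact
#'   decimal representation or [as.numeric()] for a (possibly lossy) double.
#' @examples
#' as.character(search_space_size(50000, 3)) # "20832083350000"
#' search_space_size(24, 12)
#' @export
search_space_size <- function(N, n) {
  stopifnot(length(N) == 1L, length(n) == 1L, is.finite(N), is.finite(n),
            N == trunc(N), n == trunc(n), N >= 0)
  if (n < 0 || n > N) stop("n must satisfy 0 <= n <= N")
  k <- min(n, N - n)
  r <- big_from_int(1)
  if (k > 0) {
    for (i in seq_len(k)) {
      r <- big_mul_small(r, N - k + i)
      r <- big_div_small(r, i)
    }
  }
  structure(list(digits = r, N = N, n = n), class = "sds_bigint")
}

#' @export
as.character.sds_bigint <- function(x, ...) big_to_string(x$digits)

#' @export
as.double.sds_bigint <- function(x, ...) {
  sum(x$digits * .BIG_BASE^(seq_along(x$digits) - 1))
}

#' @export
format.sds_bigint <- function(x, ...) big_to_string(x$digits)

#' @export
print.sds_bigint <- function(x, ...) {
  cat(sprintf("choose(%d, %d) = %s\n", x$N, x$n, big_to_string(x$digits)))
  invisible(x)
}
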