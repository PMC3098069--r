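#' Exact rational arithmetic for structural granularity values
#'
#' Structural granularity values on non-backbone levels are open rational
#' intervals; equality of overcrossing levels must be decidable exactly, so
#' endpoints are kept as integer numerator/denominator pairs instead of
#' floating point. Numerators and denominators stay far below 2^53 for any
#' realistic partonomy (denominators are products of small powers of 2, 3
#' and chain lengths), so base-R doubles hold them exactly.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero).
#' @return A length-2 numeric vector `c(num, den)` in lowest terms with a
#'   positive denominator.
#' @keywords internal
#' @noRd
rat <- function(num, den = 1) {
  stopifnot(length(num) == 1, length(den) == 1, den != 0,
            num == trunc(num), den == trunc(den))
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- rat_gcd(abs(num), den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  c(num = num, den = den)
}

rat_gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  if (a == 0) 1 else a
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_sub <- function(a, b) rat(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  stopifnot(b[1] != 0)
  rat(a[1] * b[2], a[2] * b[1])
}

## sign of a - b, exactly
rat_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])
rat_eq <- function(a, b) rat_cmp(a, b) == 0
rat_lt <- function(a, b) rat_cmp(a, b) < 0
rat_le <- function(a, b) rat_cmp(a, b) <= 0

rat_mid <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], 2 * a[2] * b[2])

rat_num <- function(a) a[1] / a[2]

rat_format <- function(a) {
  if (a[2] == 1) format(a[1]) else paste0(a[1], "/", a[2])
}

#' Structural granularity value
#'
#' A structural granularity value is either a fixed natural number (levels of
#' the compositional-object backbone) or an open rational interval strictly
#' between two adjacent naturals, carrying a representative point used for
#' ordering comparisons.
#'
#' @param k natural number (>= 1).
#' @return An object of class `sgv`.
#' @examples
#' sgv_natural(2)
#' sgv_interval(rat(1), rat(2))
#' @export
sgv_natural <- function(k) {
  stopifnot(length(k) == 1, k >= 1, k == trunc(k))
  structure(list(variant = "natural", k = k,
                 rep = rat(k)), class = "sgv")
}

#' @param lo,hi exact rational interval bounds (`rat()` pairs), `lo < hi`.
#' @param representative representative point, strictly inside `(lo, hi)`;
#'   defaults to the midpoint.
#' @rdname sgv_natural
#' @export
sgv_interval <- function(lo, hi, representative = rat_mid(lo, hi)) {
  stopifnot(rat_lt(lo, hi), rat_lt(lo, representative),
            rat_lt(representative, hi))
  structure(list(variant = "interval", lo = lo, hi = hi,
                 rep = representative), class = "sgv")
}

#' @param x,y `sgv` objects.
#' @rdname sgv_natural
#' @export
sgv_equal <- function(x, y) {
  stopifnot(inherits(x, "sgv"), inherits(y, "sgv"))
  if (x$variant != y$variant) return(FALSE)
  if (x$variant == "natural") return(x$k == y$k)
  rat_eq(x$lo, y$lo) && rat_eq(x$hi, y$hi) && rat_eq(x$rep, y$rep)
}

#' @export
format.sgv <- function(x, ...) {
  if (x$variant == "natural") {
    format(x$k)
  } else {
    paste0("(", rat_format(x$lo), ", ", rat_format(x$hi), ") ~ ",
           rat_format(x$rep))
  }
}

#' @export
print.sgv <- function(x, ...) {
  cat("<structural granularity value> ", format(x), "\n", sep = "")
  invisible(x)
}
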