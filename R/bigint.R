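# Minimal arbitrary-precision non-negative integer arithmetic.
#
# Numbers are stored as double vectors of base-1e4 limbs, least significant
# first. Doubles hold limb products exactly (limb * multiplier < 2^53 for
# multipliers below ~1e9), so all operations here are exact.

BIG_BASE <- 1e4

big_from_int <- function(x) {
  stopifnot(length(x) == 1L, x >= 0, x == floor(x))
  if (x == 0) return(structure(0, class = "bignum"))
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  structure(limbs, class = "bignum")
}

big_trim <- function(a) {
  k <- length(a)
  while (k > 1L && a[k] == 0) k <- k - 1L
  structure(a[seq_len(k)], class = "bignum")
}

# multiply by a machine integer m (0 <= m < ~1e9)
big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 1e9)
  if (m == 0) return(big_from_int(0))
  x <- unclass(a) * m
  carry <- 0
  out <- numeric(length(x) + 8L)
  for (i in seq_along(x)) {
    v <- x[i] + carry
    out[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  i <- length(x)
  while (carry > 0) {
    i <- i + 1L
    out[i] <- carry %% BIG_BASE
    carry <- carry %/% BIG_BASE
  }
  big_trim(structure(out[seq_len(max(i, length(x)))], class = "bignum"))
}

# exact division by a machine integer; errors if a remainder is left
big_div_small <- function(a, m) {
  stopifnot(m >= 1, m == floor(m), m < 1e9)
  x <- unclass(a)
  out <- numeric(length(x))
  rem <- 0
  for (i in rev(seq_along(x))) {
    v <- rem * BIG_BASE + x[i]
    out[i] <- v %/% m
    rem <- v %% m
  }
  if (rem != 0) stop("big_div_small: division is not exact")
  big_trim(structure(out, class = "bignum"))
}

big_add <- function(a, b) {
  x <- unclass(a); y <- unclass(b)
  k <- max(length(x), length(y))
  x <- c(x, numeric(k - length(x)))
  y <- c(y, numeric(k - length(y)))
  s <- x + y
  carry <- 0
  for (i in seq_len(k)) {
    v <- s[i] + carry
    s[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  if (carry > 0) s <- c(s, carry)
  big_trim(structure(s, class = "bignum"))
}

big_eq <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  length(a) == length(b) && all(unclass(a) == unclass(b))
}

# base-10 logarithm using the leading ~16 significant digits
big_log10 <- function(a) {
  a <- big_trim(a)
  k <- length(a)
  if (k == 1L && a[1] == 0) return(-Inf)
  top <- 0
  used <- 0L
  i <- k
  while (i >= 1L && used < 5L) {
    top <- top * BIG_BASE + a[i]
    used <- used + 1L
    i <- i - 1L
  }
  log10(top) + 4 * (k - used)
}

big_pow_small <- function(base, exponent) {
  out <- big_from_int(1)
  for (i in seq_len(exponent)) out <- big_mul_small(out, base)
  out
}

#' @export
as.character.bignum <- function(x, ...) {
  x <- big_trim(x)
  k <- length(x)
  head <- format(x[k], scientific = FALSE)
  rest <- if (k > 1L) sprintf("%04d", rev(unclass(x)[seq_len(k - 1L)])) else character(0)
  paste0(head, paste(rest, collapse = ""))
}

#' @export
print.bignum <- function(x, ...) {
  cat("<bignum> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bignum <- function(x, ...) as.character(x)
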