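# shared numeric helpers

# log10(sum(10^x)) without overflow
logsumexp10 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

#' Format a log10 probability as an order-of-magnitude exponent
#'
#' Probabilities in rarity work are reported as powers of ten. Two
#' conventions are in use: `"round"` reports the nearest power of ten
#' (raw log10 of -73.6 becomes -74), while `"floor"` reports the exponent
#' scientific notation would use (raw -123.2 becomes -124, since
#' 10^-123.2 = 6.3e-124). Both appear in published rarity tables, so both
#' are supported; the raw log10 value should always be carried alongside.
#'
#' @param log10_value Numeric, the raw base-10 logarithm.
#' @param convention `"round"` or `"floor"`.
#' @return Integer exponent(s).
#' @examples
#' format_exponent(-73.6, "round")   # -74
#' format_exponent(-123.2, "floor")  # -124
#' @export
format_exponent <- function(log10_value, convention = c("round", "floor")) {
  convention <- match.arg(convention)
  switch(convention,
    round = as.integer(round(log10_value)),
    floor = as.integer(floor(log10_value))
  )
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stream seed from one user seed; fixed offsets keep streams
# stable when generators are added. Result stays below 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 8191) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
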