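# Discovery-time and discovery-probability mathematics for undirected
# searches of sequence space, including the multi-target extension.

#' Fitted discovery-time constants
#'
#' The expected number of trials for an undirected search to first enter a
#' target of fractional size c scales as `d = A * B^L` in protein length
#' `L`. The constants were fitted to search simulations for the two
#' calibrated target sizes: `A = 2.21, B = 3.25` for c = 1/3 and
#' `A = 5.36, B = 1.56` for c = 1/2.
#'
#' @param a Coefficient (> 0).
#' @param b Base (> 1).
#' @return A list of class `discovery_constants`.
#' @export
discovery_constants <- function(a, b) {
  stopifnot(a > 0, b > 1)
  structure(list(a = a, b = b), class = "discovery_constants")
}

preset_discovery_constants <- function(c_class) {
  switch(c_class,
    one_third = discovery_constants(2.21, 3.25),
    one_half = discovery_constants(5.36, 1.56),
    stop("unknown target-size class: ", c_class)
  )
}

#' Expected discovery time of a sequence-space target
#'
#' `d = A * B^L`, returned as log10: `log10(A) + L * log10(B)`, with the
#' calibrated constants for the c = 1/3 and c = 1/2 target classes, or
#' custom constants.
#'
#' @param L Protein length.
#' @param c_class `"one_third"` or `"one_half"`.
#' @param constants Optional [discovery_constants()] overriding the class
#'   presets.
#' @return log10 of the expected number of trials.
#' @examples
#' discovery_time(238, "one_third")  # ~ 122.2, i.e. d ~ 10^122
#' @export
discovery_time <- function(L, c_class = c("one_third", "one_half"),
                           constants = NULL) {
  if (L < 0) stop("L must be >= 0")
  k <- constants %||% preset_discovery_constants(match.arg(c_class))
  stopifnot(inherits(k, "discovery_constants"))
  log10(k$a) + L * log10(k$b)
}

#' Probability of discovering the target within the search budget
#'
#' A search making `Tm` trials against an expected discovery time `d`
#' succeeds with probability `Pdt = 1 - exp(-Tm / d)`. Computed stably in
#' log10: when `Tm << d` the result is `log10(Tm) - log10(d)` to first
#' order, and a series is used for `Tm / d < 1e-8` to avoid cancellation;
#' when `Tm >> d` the probability saturates at 1 (log10 -> 0).
#'
#' @param d_log10 log10 of the expected discovery time, e.g. from
#'   [discovery_time()].
#' @param constants A [search_constants()] supplying `t_m`.
#' @return log10 of the discovery probability (<= 0).
#' @examples
#' discovery_probability(discovery_time(238, "one_third"))  # ~ -84.2
#' @export
discovery_probability <- function(d_log10, constants = search_constants()) {
  stopifnot(inherits(constants, "search_constants"), is.finite(d_log10))
  log10_ratio <- log10(constants$t_m) - d_log10
  if (log10_ratio < -8) {
    # 1 - exp(-x) = x (1 - x/2 + ...); x itself may underflow doubles, so
    # keep the leading term in log space
    x <- 10^log10_ratio
    return(log10_ratio + log1p(-x / 2) / log(10))
  }
  x <- 10^log10_ratio
  log10(-expm1(-x))
}

#' Expected time to discover one of several equivalent targets
#'
#' With `m` targets of nucleotide-space fractional size `c` for a protein
#' of length `L`, the expected discovery time is
#' `dm = (1/m) * exp(6 L (3/4 - c)^2)` trials. The 3/4 ceiling is the
#' random-sequence expectation (a random nucleotide matches with
#' probability 1/4); targets with `c >= 3/4` would cover typical random
#' sequences and are rejected.
#'
#' @param L Protein length.
#' @param c Target fraction in (0, 3/4).
#' @param m Number of targets (>= 1).
#' @return log10 of the expected number of trials:
#'   `6 L (3/4 - c)^2 / ln(10) - log10(m)`.
#' @export
multi_target_time <- function(L, c, m = 1) {
  if (L < 1) stop("L must be positive")
  if (c >= 3 / 4) stop("c must be below 3/4 (target would cover typical sequences)")
  if (c <= 0) stop("c must be positive")
  if (m < 1) stop("m must be >= 1")
  6 * L * (3 / 4 - c)^2 / log(10) - log10(m)
}

#' Smallest target discoverable within a trial budget
#'
#' Inverts [multi_target_time()]: for a search limited to `10^d_max`
#' trials over `m` targets, the smallest discoverable target fraction is
#' `cmin = 3/4 - sqrt(ln(m * 10^d_max) / (6 L))`, reported as a whole
#' percent. Weakly increasing in `L` and weakly decreasing in `m`.
#'
#' @param L Protein length.
#' @param d_max log10 of the trial budget.
#' @param m Number of targets.
#' @return Integer percent.
#' @examples
#' minimum_discoverable_target(250, 40)  # 50
#' @export
minimum_discoverable_target <- function(L, d_max, m = 1) {
  if (L < 1) stop("L must be positive")
  if (m < 1) stop("m must be >= 1")
  ln_md <- log(m) + d_max * log(10)
  if (ln_md > 6 * L * (3 / 4)^2)
    stop("trial budget exceeds the whole-space search time: cmin undefined")
  cmin <- 3 / 4 - sqrt(ln_md / (6 * L))
  as.integer(round(100 * cmin))
}
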