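# Combinatorics of amino acid sequence space. All probabilities are carried
# as log10 reals; counts are exact via the internal bignum arithmetic.

# log10 of the number of sequences at Hamming distance n from a length-L
# reference: C(L, n) * 19^n
log10_nseq <- function(L, n) {
  lchoose(L, n) / log(10) + n * log10(19)
}

#' Count sequences at an exact Hamming distance
#'
#' The number of amino acid sequences of length `L` that differ from a
#' fixed reference sequence in exactly `n` positions is
#' `C(L, n) * 19^n`: choose the positions, then one of the 19 alternative
#' residues at each. The count is returned as an exact arbitrary-precision
#' integer (class `bignum`; use `as.character()` for its decimal form).
#'
#' @param L Positive integer sequence length.
#' @param n Integer distance, `0 <= n <= L`.
#' @return A `bignum` holding the exact count.
#' @examples
#' as.character(count_sequences_at_distance(5, 2))  # "3610"
#' @export
count_sequences_at_distance <- function(L, n) {
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  if (n < 0 || n > L) stop("n must lie in [0, L]")
  # iterative exact binomial: T(k) = T(k-1) * (L - k + 1) * 19 / k
  acc <- big_from_int(1)
  if (n == 0) return(acc)
  for (k in seq_len(n)) {
    acc <- big_mul_small(acc, (L - k + 1) * 19)
    acc <- big_div_small(acc, k)
  }
  acc
}

#' Density of functional sequences over Hamming distance
#'
#' Combines the survival model with the sequence-count combinatorics to
#' give PDF(n), the probability that a randomly chosen *functional*
#' sequence lies at Hamming distance `n` from the wildtype:
#' `PDF(n) = P(n) * Nseq(n) / NFS`, where `NFS` normalises over
#' `n = 0..L`. All arithmetic is in log10 space, so no overflow occurs for
#' any protein length. The survival model is an extrapolation for large
#' `n` (epistasis strength is only measured at small `n`), so the density
#' is quantitatively reliable only near its mode and is intended for
#' qualitative comparison between proteins.
#'
#' @param fit A [hyperexp_fit()].
#' @param L Protein length (amino acids).
#' @return A data frame of class `functional_density` with columns `n`,
#'   `log10_weight` (`log10 P(n) + log10 Nseq(n)`), and `pdf` (normalised),
#'   plus attribute `log10_nfs` (log10 of the functional-sequence count
#'   relative to P in [0,1] units).
#' @examples
#' d <- functional_density(hyperexp_fit(0.104, 0.019), L = 263)
#' d$n[which.max(d$pdf)]  # mode near n = 91
#' @export
functional_density <- function(fit, L) {
  fit <- as_hyperexp_fit(fit)
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  n <- 0:L
  log10_p <- (-fit$alpha * n - fit$beta * n^2) / log(10)
  w <- log10_p + log10_nseq(L, n)
  log_nfs <- logsumexp10(w)
  out <- data.frame(n = n, log10_weight = w, pdf = 10^(w - log_nfs))
  attr(out, "log10_nfs") <- log_nfs
  attr(out, "fit") <- fit
  attr(out, "L") <- L
  class(out) <- c("functional_density", "data.frame")
  out
}

#' Probability that a random sequence lies within a target region
#'
#' The in-target probability is the number of sequences within Hamming
#' distance `nb` of the wildtype divided by all `20^L` sequences:
#' `Pt = sum_{n=0}^{nb} C(L, n) 19^n / 20^L`. `"exact"` mode performs the
#' summation in arbitrary-precision integers and takes one logarithm at
#' the end; `"log"` mode uses log-sum-exp in double precision. The two
#' agree to well under 1e-9 and the exact mode is the default.
#'
#' @param L Protein length.
#' @param nb Target boundary in substitutions, `0 <= nb <= L`.
#' @param mode `"exact"` or `"log"`.
#' @return log10 of the in-target probability (a non-positive real;
#'   0 exactly when `nb == L`).
#' @examples
#' prob_in_target(263, 150)  # ~ -73.6, i.e. Pt ~ 10^-74
#' @export
prob_in_target <- function(L, nb, mode = c("exact", "log")) {
  mode <- match.arg(mode)
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  if (nb < 0 || nb > L) stop("nb must lie in [0, L]")
  if (nb == L) return(0)
  if (mode == "log") {
    n <- 0:nb
    return(logsumexp10(log10_nseq(L, n)) - L * log10(20))
  }
  term <- big_from_int(1)
  total <- big_from_int(1)
  if (nb >= 1) for (k in seq_len(nb)) {
    term <- big_div_small(big_mul_small(term, (L - k + 1) * 19), k)
    total <- big_add(total, term)
  }
  big_log10(total) - L * log10(20)
}

# default nucleotide-to-amino-acid target fraction map
CA_MAP <- list("1/3" = 0.57, "1/2" = 0.77)

match_c_fraction <- function(c) {
  if (abs(c - 1 / 3) < 1e-9) return("1/3")
  if (abs(c - 1 / 2) < 1e-9) return("1/2")
  NA_character_
}

#' Build a target region from a nucleotide- or amino-acid-space fraction
#'
#' A target is the neighbourhood of the wildtype within which essentially
#' all functional sequences reside, specified as the maximum fraction of
#' positions that may differ: `c` in nucleotide space or `ca` in amino
#' acid space. Only the calibrated pairs c = 1/3 <-> ca = 0.57 and
#' c = 1/2 <-> ca = 0.77 are mapped automatically; other fractions must
#' supply `ca` directly. The boundary in substitutions is
#' `nb = floor(ca * L)` by default; published conversions are not fully
#' consistent on rounding, so `rounding = "round"` is available.
#'
#' @param c Nucleotide-space fraction (1/3 or 1/2), or `NULL`.
#' @param ca Amino-acid-space fraction in (0, 1], or `NULL` to map from
#'   `c`.
#' @param L Protein length.
#' @param rounding `"floor"` (default) or `"round"` for the `ca * L`
#'   conversion.
#' @return A list of class `target_region` with elements `c`, `ca`, `nb`,
#'   `L`.
#' @examples
#' target_from_fraction(c = 1/3, L = 238)$nb  # 135
#' @export
target_from_fraction <- function(c = NULL, ca = NULL, L,
                                 rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  if (is.null(ca)) {
    if (is.null(c)) stop("supply c or ca")
    key <- match_c_fraction(c)
    if (is.na(key))
      stop("no calibrated amino-acid mapping for c = ", signif(c, 4),
           "; supply ca directly")
    ca <- CA_MAP[[key]]
  }
  if (ca <= 0 || ca > 1) stop("ca must lie in (0, 1]")
  nb <- switch(rounding, floor = floor(ca * L), round = round(ca * L))
  structure(list(c = c, ca = ca, nb = as.integer(nb), L = as.integer(L)),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat("Target region: nb =", x$nb, "of L =", x$L,
      sprintf("(ca = %.2f%s)\n", x$ca,
              if (!is.null(x$c)) sprintf(", c = %.3g", x$c) else ""))
  invisible(x)
}

#' Radial functional-sequence-heat map data
#'
#' Exports the rows of a [functional_density()] as a radial-map table
#' (radius = Hamming distance `n`, shade proportional to `pdf`) together
#' with the boundary radii of any target regions, for plotting a
#' functional sequence heat (FSH) map. Pure data export; no rendering is
#' performed.
#'
#' @param density A [functional_density()].
#' @param boundaries A list of [target_from_fraction()] regions (may be
#'   empty).
#' @return A data frame with columns `n`, `pdf`, `log10_weight` and an
#'   attribute `boundaries`: a data frame of `label`, `radius` rows (zero
#'   rows when no boundaries given).
#' @export
fsh_map_data <- function(density, boundaries = list()) {
  stopifnot(inherits(density, "functional_density"))
  out <- as.data.frame(density)[, c("n", "pdf", "log10_weight")]
  b <- if (length(boundaries)) {
    data.frame(
      label = vapply(boundaries, function(t) {
        if (!is.null(t$c)) sprintf("c = %.3g", t$c) else sprintf("ca = %.2f", t$ca)
      }, character(1)),
      radius = vapply(boundaries, function(t) as.numeric(t$nb), numeric(1))
    )
  } else {
    data.frame(label = character(0), radius = numeric(0))
  }
  attr(out, "boundaries") <- b
  out
}

#' @rdname fsh_map_data
#' @param x A `functional_density`.
#' @param ... Passed to [graphics::image()]-style shading (unused).
#' @details `plot.functional_density()` draws a minimal reference FSH map
#'   with base graphics: concentric shading by `pdf` and dashed rings at
#'   the supplied boundary radii.
#' @export
plot.functional_density <- function(x, boundaries = list(), ...) {
  tab <- fsh_map_data(x, boundaries)
  r_max <- max(c(tab$n[tab$pdf > 1e-12], attr(tab, "boundaries")$radius, 1))
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  plot(NA, xlim = c(-r_max, r_max), ylim = c(-r_max, r_max), axes = FALSE,
       xlab = "", ylab = "", main = "Functional sequence heat map")
  shade <- tab$pdf / max(tab$pdf)
  theta <- seq(0, 2 * pi, length.out = 120)
  for (i in rev(seq_len(nrow(tab)))) {
    if (shade[i] < 1e-6) next
    graphics::polygon(tab$n[i] * cos(theta), tab$n[i] * sin(theta),
                      border = grDevices::grey(1 - shade[i]))
  }
  bd <- attr(tab, "boundaries")
  for (j in seq_len(nrow(bd))) {
    graphics::lines(bd$radius[j] * cos(theta), bd$radius[j] * sin(theta), lty = 2)
    graphics::text(0, bd$radius[j], bd$label[j], pos = 3, cex = 0.8)
  }
  invisible(tab)
}
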