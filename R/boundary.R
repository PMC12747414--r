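# Target-boundary estimation and the upper-bound rarity estimators.

#' Discoverability thresholds and search budget
#'
#' The maximum number of distinct gene variants that could have been
#' trialled over Earth's history is about `Tm = 1e38`; its reciprocal sets
#' the discoverability threshold `Pth ~ 1e-40` below which a functional
#' sequence is effectively undiscoverable by an undirected search. For
#' multicellular eukaryotes (smaller populations, longer generations) the
#' effective threshold is nearer `1e-20`.
#'
#' @param t_m Maximum number of trials.
#' @param p_th Discoverability threshold probability.
#' @param m Number of equivalent targets in the search space.
#' @return A list of class `search_constants`.
#' @export
search_constants <- function(t_m = 1e38, p_th = 1e-40, m = 1) {
  stopifnot(t_m > 0, p_th > 0, p_th < 1, m >= 1)
  structure(list(t_m = t_m, p_th = p_th, m = m), class = "search_constants")
}

#' Eukaryote-scale discoverability threshold
#' @return `search_constants` with `p_th = 1e-20`.
#' @rdname search_constants
#' @export
search_constants_eukaryote <- function() search_constants(p_th = 1e-20)

#' Target boundary from a tolerated-mutation fraction
#'
#' Starting from a measured survival probability `p_n0` at depth `n0`,
#' each further substitution is tolerated with probability `ptol`, so the
#' survival bound falls below the discoverability floor `p_min` after
#' `log(p_min / p_n0) / log(ptol)` more steps:
#' `nb = log(p_min / p_n0) / log(ptol) + n0`, rounded to the nearest
#' integer by default.
#'
#' @param p_n0 Survival probability at the reference depth, in (0, 1].
#' @param ptol Tolerated-mutation fraction in (0, 1).
#' @param n0 Reference depth (substitutions).
#' @param p_min Discoverability floor; defaults to `Pth = 1e-40`.
#' @param rounding `"round"` (default), `"floor"`, or `"ceiling"`.
#' @return Integer target boundary `nb`.
#' @examples
#' boundary_from_tolerance(0.19, 1 / 3, 7)     # 89
#' boundary_from_tolerance(0.006, 1 / 2, 14)   # 139
#' @export
boundary_from_tolerance <- function(p_n0, ptol, n0, p_min = 1e-40,
                                    rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (ptol <= 0 || ptol >= 1) stop("ptol must lie strictly inside (0, 1)")
  if (p_min <= 0 || p_n0 <= 0 || p_n0 > 1) stop("probabilities must lie in (0, 1]")
  if (p_min >= p_n0) stop("p_min must be below p_n0")
  raw <- log(p_min / p_n0) / log(ptol) + n0
  as.integer(switch(rounding, round = round(raw), floor = floor(raw),
                    ceiling = ceiling(raw)))
}

#' Upper bound on the functional fraction inside the target
#'
#' If each of the `nb` substitutions available inside the target is
#' tolerated with probability at most `ptol`, the fraction of in-target
#' sequences that remain functional is bounded by `Pubt = ptol^nb`.
#'
#' @param ptol Tolerated-mutation fraction in (0, 1).
#' @param nb Target boundary (substitutions), >= 0.
#' @return log10 of the bound (`nb * log10(ptol)`).
#' @examples
#' prob_functional_in_target(1 / 3, 150)  # ~ -71.6, i.e. 10^-72
#' @export
prob_functional_in_target <- function(ptol, nb) {
  if (ptol <= 0 || ptol >= 1) stop("ptol must lie strictly inside (0, 1)")
  if (nb < 0) stop("nb must be >= 0")
  nb * log10(ptol)
}

#' Composite global rarity estimate
#'
#' The global upper bound on the functional fraction is the probability of
#' landing in the target times the functional fraction inside it:
#' `Pub = Pt * Pubt`. On the raw log10 scale this is a plain sum. The
#' published order-of-magnitude chains combine the *individually
#' formatted* exponents, so the formatted composite exponent here is the
#' sum of the two component exponents under the declared convention (not
#' the formatted raw sum); the raw value is always carried alongside.
#'
#' @param log10_pt log10 in-target probability (<= 0), from
#'   [prob_in_target()].
#' @param log10_pubt log10 in-target functional bound (<= 0), from
#'   [prob_functional_in_target()].
#' @param convention Exponent formatting, `"round"` or `"floor"`; see
#'   [format_exponent()].
#' @param nb_used,ptol_used Optional provenance echoed into the report.
#' @return A list of class `rarity_report`: raw `log10_pt`, `log10_pubt`,
#'   `log10_pub`, formatted `exponents` (`pt`, `pubt`, `pub`),
#'   `convention`, `nb_used`, `ptol_used`.
#' @examples
#' r <- composite_rarity(prob_in_target(263, 150),
#'                       prob_functional_in_target(1 / 3, 150))
#' r$exponents$pub  # -146
#' @export
composite_rarity <- function(log10_pt, log10_pubt,
                             convention = c("round", "floor"),
                             nb_used = NA_integer_, ptol_used = NA_real_) {
  convention <- match.arg(convention)
  if (log10_pt > 0 || log10_pubt > 0) stop("log10 probabilities must be <= 0")
  e_pt <- format_exponent(log10_pt, convention)
  e_pubt <- format_exponent(log10_pubt, convention)
  structure(
    list(
      log10_pt = log10_pt, log10_pubt = log10_pubt,
      log10_pub = log10_pt + log10_pubt,
      exponents = list(pt = e_pt, pubt = e_pubt, pub = e_pt + e_pubt),
      convention = convention,
      nb_used = nb_used, ptol_used = ptol_used
    ),
    class = "rarity_report"
  )
}

#' @export
print.rarity_report <- function(x, ...) {
  cat("Rarity report (exponent convention: ", x$convention, ")\n", sep = "")
  cat(sprintf("  Pt   = 10^%d (raw log10 %.3f)\n", x$exponents$pt, x$log10_pt))
  cat(sprintf("  Pubt = 10^%d (raw log10 %.3f)\n", x$exponents$pubt, x$log10_pubt))
  cat(sprintf("  Pub  = 10^%d (raw log10 %.3f)\n", x$exponents$pub, x$log10_pub))
  if (!is.na(x$nb_used)) cat("  nb used:", x$nb_used, "\n")
  if (!is.na(x$ptol_used)) cat(sprintf("  Ptol used: %.4g\n", x$ptol_used))
  invisible(x)
}

#' Whole-length rarity bound from the tolerated fraction alone
#'
#' When no target can be defined (no survival curve, or no negative
#' epistasis), every one of the `L` positions is treated as tolerating a
#' substitution with probability `ptol`, giving `Pub = ptol^L`. This is
#' always a weaker (larger) bound than the target-based composite, since
#' it assumes functional sequences outside the target are as dense as
#' inside.
#'
#' @param ptol Tolerated-mutation fraction in (0, 1].
#' @param L Protein length.
#' @return log10 of the bound (`L * log10(ptol)`).
#' @export
rarity_from_tolerance <- function(ptol, L) {
  if (ptol <= 0 || ptol > 1) stop("ptol must lie in (0, 1]")
  if (L < 1) stop("L must be positive")
  L * log10(ptol)
}

#' Effective tolerated fraction implied by a rarity estimate
#'
#' Inverts [rarity_from_tolerance()]: given an external rarity estimate
#' `Pfs` for a protein of length `L`, the per-position tolerated fraction
#' that would reproduce it is `ptol = 10^(log10_pfs / L)`, reported as a
#' whole percent.
#'
#' @param log10_pfs log10 of the rarity estimate (< 0).
#' @param L Protein length.
#' @return Integer percent.
#' @examples
#' tolerance_from_rarity(-24, 35)  # 21
#' @export
tolerance_from_rarity <- function(log10_pfs, L) {
  if (log10_pfs >= 0) stop("log10_pfs must be negative")
  if (L < 1) stop("L must be positive")
  as.integer(round(100 * 10^(log10_pfs / L)))
}

#' Rarity bound from the non-destabilizing mutation fraction
#'
#' For proteins with only stability-change (ddG) data, the fraction of
#' non-destabilizing mutations `Pnd` stands in for the tolerated fraction
#' and the whole-length bound becomes `Pub = Pnd^L`. Published tables of
#' this quantity use the scientific-notation (floor) exponent convention;
#' use [format_exponent()] with `"floor"` to format.
#'
#' @param pnd Non-destabilizing fraction in (0, 1].
#' @param L Protein length.
#' @return log10 of the bound.
#' @examples
#' format_exponent(rarity_from_nondestabilizing(0.34, 263), "floor")  # -124
#' @export
rarity_from_nondestabilizing <- function(pnd, L) {
  if (pnd <= 0 || pnd > 1) stop("pnd must lie in (0, 1]")
  if (L < 1) stop("L must be positive")
  L * log10(pnd)
}
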