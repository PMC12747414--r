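# Stability-change (ddG) distributions: two-component Gaussian mixture
# model, tolerance-threshold calibration, and empirical non-destabilizing
# fractions from per-mutation ddG tables.
#
# Sign convention throughout: ddG > 0 destabilizes. "Non-destabilizing"
# means ddG below the cutoff, which includes stabilizing (negative)
# mutations.

#' Two-component Gaussian mixture for ddG distributions
#'
#' Empirical distributions of single-mutation stability changes are well
#' described by a mixture of two Gaussians (a narrow near-neutral
#' component and a broader destabilizing one). Units are kcal/mol.
#'
#' @param w Weight of component 1 in `[0, 1]`.
#' @param mu1,mu2 Component means (kcal/mol).
#' @param s1,s2 Component standard deviations (> 0).
#' @return A list of class `bigaussian`.
#' @examples
#' bigaussian(w = 0.3, mu1 = -0.8, s1 = 0.6, mu2 = 1.6, s2 = 1.2)
#' @export
bigaussian <- function(w, mu1, s1, mu2 = mu1, s2 = s1) {
  stopifnot(w >= 0, w <= 1, s1 > 0, s2 > 0,
            is.finite(mu1), is.finite(mu2))
  structure(list(w = w, mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2),
            class = "bigaussian")
}

#' Mixture distribution function and density
#'
#' `mixture_cdf()` is `w * Phi((x - mu1)/s1) + (1 - w) * Phi((x - mu2)/s2)`;
#' `mixture_pdf()` is the corresponding density.
#'
#' @param model A [bigaussian()].
#' @param x ddG value(s) in kcal/mol.
#' @return Probabilities in `[0, 1]` (cdf) or densities (pdf).
#' @export
mixture_cdf <- function(model, x) {
  stopifnot(inherits(model, "bigaussian"))
  model$w * stats::pnorm(x, model$mu1, model$s1) +
    (1 - model$w) * stats::pnorm(x, model$mu2, model$s2)
}

#' @rdname mixture_cdf
#' @export
mixture_pdf <- function(model, x) {
  stopifnot(inherits(model, "bigaussian"))
  model$w * stats::dnorm(x, model$mu1, model$s1) +
    (1 - model$w) * stats::dnorm(x, model$mu2, model$s2)
}

#' Calibrate the destabilization cutoff from a tolerated fraction
#'
#' Finds the ddG value below which a fraction `ptol` of mutations fall:
#' the `ptol`-quantile of the mixture, by monotone root finding on
#' [mixture_cdf()]. Applied to a benchmark protein's ddG distribution with
#' its measured tolerated-mutation fraction, this yields the cutoff `Gth`
#' separating tolerated from destabilizing mutations (close to
#' 0.5 kcal/mol for the beta-lactamase benchmark at Ptol = 1/3).
#'
#' @param model A [bigaussian()].
#' @param ptol Target cumulative probability in (0, 1).
#' @param tol Root-finding tolerance in kcal/mol.
#' @return The threshold in kcal/mol.
#' @export
calibrate_threshold <- function(model, ptol, tol = 1e-9) {
  stopifnot(inherits(model, "bigaussian"))
  if (ptol <= 0 || ptol >= 1) stop("ptol must lie strictly inside (0, 1)")
  lo <- min(model$mu1 - 10 * model$s1, model$mu2 - 10 * model$s2)
  hi <- max(model$mu1 + 10 * model$s1, model$mu2 + 10 * model$s2)
  while (mixture_cdf(model, lo) > ptol) lo <- lo - (hi - lo)
  while (mixture_cdf(model, hi) < ptol) hi <- hi + (hi - lo)
  stats::uniroot(function(x) mixture_cdf(model, x) - ptol,
                 lower = lo, upper = hi, tol = tol)$root
}

#' Model-based non-destabilizing fraction
#'
#' `Pnd = P(ddG < g_th)` under the mixture model: the fraction of new
#' mutations whose stability cost is below the cutoff and that are
#' therefore generally tolerated once a protein has drifted past its
#' stability threshold. Common cutoffs are 0.5 kcal/mol (high-specificity
#' benchmark) and the more conservative 1.0 kcal/mol.
#'
#' @param model A [bigaussian()].
#' @param g_th Cutoff in kcal/mol.
#' @return Probability in (0, 1).
#' @export
nondestabilizing_fraction_model <- function(model, g_th = 0.5) {
  mixture_cdf(model, g_th)
}

#' Per-mutation ddG record table
#'
#' One stability change per recorded mutation, grouped by protein, in the
#' style of a FireProtDB export. Positive ddG destabilizes.
#'
#' @param protein Character vector of protein identifiers.
#' @param ddg Numeric ddG values (kcal/mol), all finite.
#' @param position,wt,mut Optional mutation annotations.
#' @return A data frame of class `ddg_table`.
#' @export
ddg_table <- function(protein, ddg, position = NULL, wt = NULL, mut = NULL) {
  if (length(protein) != length(ddg)) stop("protein and ddg lengths differ")
  if (any(!is.finite(ddg))) stop("all ddg values must be finite")
  out <- data.frame(protein = as.character(protein), ddg = as.numeric(ddg))
  if (!is.null(position)) out$position <- as.integer(position)
  if (!is.null(wt)) out$wt <- as.character(wt)
  if (!is.null(mut)) out$mut <- as.character(mut)
  class(out) <- c("ddg_table", "data.frame")
  out
}

#' Empirical non-destabilizing fractions per protein
#'
#' For each protein with at least `min_records` ddG entries, the fraction
#' of entries strictly below the cutoff `g_th` (ties at the cutoff count
#' as destabilizing). Proteins with fewer records are excluded and listed
#' in the `excluded` attribute; record-poor proteins give unstable
#' fractions, hence the default floor of 30 records. Duplicate
#' measurements of the same mutation are counted as separate entries
#' unless `dedup = TRUE`, which averages ddG over identical
#' (protein, position, wt, mut) annotations first.
#'
#' @param table A [ddg_table()].
#' @param g_th Cutoff in kcal/mol.
#' @param min_records Minimum entries per protein (default 30).
#' @param dedup Average duplicate mutation records before counting.
#' @return A data frame with columns `protein`, `n_records`, `pnd`, with
#'   attribute `excluded` naming the proteins filtered out. Empty (with a
#'   warning) when the table has no rows.
#' @examples
#' tab <- ddg_table(rep("p", 4), c(-1, 0, 1, 2))
#' nondestabilizing_fraction_empirical(tab, g_th = 0.5, min_records = 1)
#' @export
nondestabilizing_fraction_empirical <- function(table, g_th = 0.5,
                                                min_records = 30, dedup = FALSE) {
  stopifnot(inherits(table, "ddg_table"))
  if (nrow(table) == 0) {
    warning("empty ddG table: no fractions computed")
    out <- data.frame(protein = character(0), n_records = integer(0),
                      pnd = numeric(0))
    attr(out, "excluded") <- character(0)
    return(out)
  }
  dat <- as.data.frame(table)
  if (dedup) {
    keys <- c("protein", intersect(c("position", "wt", "mut"), names(dat)))
    dat <- stats::aggregate(dat["ddg"], dat[keys], mean)
  }
  counts <- table(dat$protein)
  keep <- names(counts)[counts >= min_records]
  excluded <- setdiff(names(counts), keep)
  dat <- dat[dat$protein %in% keep, , drop = FALSE]
  out <- if (nrow(dat)) {
    agg <- stats::aggregate(list(pnd = dat$ddg < g_th),
                            list(protein = dat$protein), mean)
    agg$n_records <- as.integer(counts[agg$protein])
    agg[, c("protein", "n_records", "pnd")]
  } else {
    data.frame(protein = character(0), n_records = integer(0), pnd = numeric(0))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Per-protein rarity summary from a ddG table
#'
#' Convenience wrapper producing, for each sufficiently recorded protein,
#' the empirical Pnd at both standard cutoffs and the implied whole-length
#' rarity bound `Pnd^L`, plus flags against the global (`1e-40`) and
#' eukaryotic (`1e-20`) discoverability thresholds. Protein lengths are
#' supplied as a named vector; proteins without a length get `NA` bounds.
#'
#' @param table A [ddg_table()].
#' @param lengths Named numeric vector of protein lengths (aa).
#' @param cutoffs ddG cutoffs in kcal/mol.
#' @param min_records Minimum records per protein.
#' @return A data frame with one row per protein and cutoff: `protein`,
#'   `g_th`, `n_records`, `pnd`, `log10_pub`, `exponent_floor`,
#'   `below_pth`, `below_eukaryote_pth`.
#' @export
ddg_rarity_summary <- function(table, lengths, cutoffs = c(0.5, 1.0),
                               min_records = 30) {
  rows <- lapply(cutoffs, function(g) {
    fr <- nondestabilizing_fraction_empirical(table, g_th = g,
                                              min_records = min_records)
    if (nrow(fr) == 0) return(NULL)
    L <- unname(lengths[fr$protein])
    lp <- mapply(function(p, l) {
      if (is.na(l)) return(NA_real_)
      if (p <= 0) return(-Inf)
      rarity_from_nondestabilizing(min(p, 1), l)
    }, fr$pnd, L)
    data.frame(
      protein = fr$protein, g_th = g, n_records = fr$n_records, pnd = fr$pnd,
      log10_pub = lp,
      exponent_floor = ifelse(is.na(lp), NA_integer_,
                              format_exponent(lp, "floor")),
      below_pth = lp < -40,
      below_eukaryote_pth = lp < -20
    )
  })
  do.call(rbind, rows)
}
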