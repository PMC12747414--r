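#' Construct a mutational-survival curve
#'
#' A survival curve records, for increasing numbers `n` of nonsynonymous
#' amino acid substitutions, the proportion of clones that remain
#' functional — the empirical P(n) from a mutational drift experiment
#' without selection between rounds. Either proportions or raw
#' assayed/functional counts may be supplied; when counts are present the
#' proportion must equal `functional / assayed` exactly.
#'
#' @param n Integer vector of substitution counts, strictly increasing,
#'   all >= 0.
#' @param prop Proportions functional in `[0, 1]`. May be omitted when
#'   counts are given.
#' @param assayed,functional Optional per-`n` clone counts.
#' @return A data frame of class `survival_curve` with columns `n`,
#'   `prop`, and (if given) `assayed`, `functional`.
#' @examples
#' survival_curve(n = 0:3, prop = c(1, 0.8, 0.55, 0.4))
#' @export
survival_curve <- function(n, prop = NULL, assayed = NULL, functional = NULL) {
  n <- as.integer(n)
  if (any(n < 0)) stop("substitution counts must be >= 0")
  if (any(diff(n) <= 0)) stop("substitution counts must be strictly increasing")
  if (!is.null(assayed) || !is.null(functional)) {
    if (is.null(assayed) || is.null(functional))
      stop("assayed and functional counts must be given together")
    if (length(assayed) != length(n) || length(functional) != length(n))
      stop("counts must have one entry per n")
    if (any(assayed <= 0)) stop("assayed counts must be positive")
    if (any(functional < 0)) stop("functional counts must be non-negative")
    if (any(functional > assayed)) stop("functional counts cannot exceed assayed counts")
    p <- functional / assayed
    if (!is.null(prop) && any(abs(prop - p) > 1e-12))
      stop("prop must equal functional / assayed exactly")
    prop <- p
  }
  if (is.null(prop)) stop("either prop or counts are required")
  if (length(prop) != length(n)) stop("prop must have one entry per n")
  if (any(prop < 0 | prop > 1)) stop("proportions must lie in [0, 1]")
  out <- data.frame(n = n, prop = as.numeric(prop))
  if (!is.null(assayed)) {
    out$assayed <- as.integer(assayed)
    out$functional <- as.integer(functional)
  }
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Construct a hyper-exponential fit object by hand
#'
#' The hyper-exponential mutational response is
#' `P(n) = exp(-alpha * n - beta * n^2)`: `alpha` is the initial
#' per-substitution exponential decline and `beta` the rate at which the
#' decline accelerates, i.e. the strength of negative epistasis. Published
#' parameter sets can be wrapped with this constructor; fits from data come
#' from [fit_response()].
#'
#' @param alpha,beta Model parameters (per substitution and per
#'   substitution squared). `alpha` may be negative (observed for GFP);
#'   `beta > 0` signals negative epistasis.
#' @param sigma_alpha,sigma_beta One-standard-deviation parameter errors
#'   (non-negative; `NA` when unknown).
#' @param r2_hyper,r2_exp Coefficients of determination of the
#'   hyper-exponential and the nested exponential (`beta = 0`) fit.
#' @param epistasis_k Multiple of `sigma_beta` that `beta` must exceed for
#'   the fit to be flagged epistatic (default 2).
#' @return An object of class `hyperexp_fit`.
#' @examples
#' hyperexp_fit(alpha = 0.104, beta = 0.019)
#' @export
hyperexp_fit <- function(alpha, beta, sigma_alpha = NA_real_, sigma_beta = NA_real_,
                         r2_hyper = NA_real_, r2_exp = NA_real_, epistasis_k = 2) {
  if (!is.na(sigma_alpha) && sigma_alpha < 0) stop("sigma_alpha must be >= 0")
  if (!is.na(sigma_beta) && sigma_beta < 0) stop("sigma_beta must be >= 0")
  structure(
    list(
      alpha = alpha, beta = beta,
      sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
      r2_hyper = r2_hyper, r2_exp = r2_exp,
      epistatic = if (is.na(sigma_beta)) NA else beta >= epistasis_k * sigma_beta,
      epistasis_k = epistasis_k
    ),
    class = "hyperexp_fit"
  )
}

as_hyperexp_fit <- function(fit) {
  if (inherits(fit, "hyperexp_fit")) return(fit)
  if (is.list(fit) && !is.null(fit$alpha) && !is.null(fit$beta))
    return(hyperexp_fit(fit$alpha, fit$beta))
  stop("expected a hyperexp_fit (or a list with alpha and beta)")
}

#' Evaluate the hyper-exponential survival model
#'
#' Returns `P(n) = exp(-alpha * n - beta * n^2)`, the modelled probability
#' that a protein retains function after `n` nonsynonymous substitutions.
#' `P(0)` is 1 by construction.
#'
#' @param fit A [hyperexp_fit()] (or list with `alpha`, `beta`).
#' @param n Non-negative integer vector of substitution counts.
#' @return Numeric vector of model probabilities.
#' @examples
#' eval_pn(hyperexp_fit(0.104, 0.019), 7)    # ~0.19
#' eval_pn(hyperexp_fit(-0.047, 0.054), 10)  # ~0.007
#' @export
eval_pn <- function(fit, n) {
  fit <- as_hyperexp_fit(fit)
  if (any(n < 0)) stop("n must be >= 0")
  exp(-fit$alpha * n - fit$beta * n^2)
}

# sum of squared residuals -> R^2 against the mean of included proportions
r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Fit the hyper-exponential model to a survival curve
#'
#' Unweighted nonlinear least squares of
#' `P(n) = exp(-alpha * n - beta * n^2)` on the linear proportion scale
#' (Levenberg-Marquardt), together with the nested exponential model
#' (`beta = 0`) for comparison. Parameter standard errors come from the
#' fit covariance; R-squared is computed against the mean of the included
#' proportions for both models. Because the exponential is the nested
#' special case, `r2_hyper >= r2_exp` always holds for a converged fit.
#'
#' Both parameters are unconstrained: a negative fitted `alpha` (as seen
#' for GFP, where single mutants outperform the model) is legitimate. The
#' fit is flagged `epistatic` when `beta >= epistasis_k * sigma_beta`.
#'
#' With `errors = "binomial"` (available when the curve carries clone
#' counts) the point estimates come from an iteratively reweighted fit
#' with the known binomial sampling variance `p (1 - p) / assayed`, and
#' the parameter covariance is the absolute-sigma form
#' `(J' V^-1 J)^-1` — no residual scale is estimated, so the reported
#' sigmas are calibrated even with few points. The default `"estimated"`
#' mode scales the covariance by the pooled residual variance; with ~10
#' points that makes a 3-sigma criterion effectively a t-test and the
#' sigmas run slightly optimistic. R-squared values are always the
#' descriptive unweighted linear-scale statistics, so the nested-model
#' ordering `r2_hyper >= r2_exp` holds in every mode.
#'
#' @param curve A [survival_curve()].
#' @param max_n Optional cap: points with `n > max_n` are excluded.
#' @param drop_zeros Drop points with `prop == 0` before fitting (default
#'   keeps them; they inform the tail).
#' @param start Initial `(alpha, beta)` guess; the default `(0.1, 0.01)`
#'   is the order of magnitude of published fits.
#' @param epistasis_k Epistasis flag threshold in multiples of
#'   `sigma_beta`.
#' @param errors `"estimated"` (unweighted fit, covariance scaled by the
#'   residual variance) or `"binomial"` (known-variance weights and
#'   absolute-sigma covariance; requires counts).
#' @return A `hyperexp_fit` with elements `alpha`, `beta`, `sigma_alpha`,
#'   `sigma_beta`, `r2_hyper`, `r2_exp`, `epistatic`, plus `n_used`.
#' @examples
#' cv <- survival_curve(0:10, prop = eval_pn(hyperexp_fit(0.104, 0.019), 0:10))
#' fit_response(cv)
#' @export
fit_response <- function(curve, max_n = NULL, drop_zeros = FALSE,
                         start = c(alpha = 0.1, beta = 0.01), epistasis_k = 2,
                         errors = c("estimated", "binomial")) {
  stopifnot(inherits(curve, "survival_curve"))
  errors <- match.arg(errors)
  dat <- as.data.frame(curve)
  if (!is.null(max_n)) dat <- dat[dat$n <= max_n, , drop = FALSE]
  if (drop_zeros) dat <- dat[dat$prop > 0, , drop = FALSE]
  if (nrow(dat) < 3L)
    stop("fit infeasible: at least 3 usable points are required (got ", nrow(dat), ")")
  if (errors == "binomial" && is.null(dat$assayed))
    stop("errors = \"binomial\" requires a curve with assayed/functional counts")

  fit_exp <- tryCatch(
    minpack.lm::nlsLM(prop ~ exp(-a * n), data = dat,
                      start = list(a = unname(start[1])),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ", conditionMessage(e))
  )
  a_exp <- coef(fit_exp)[["a"]]

  starts <- list(
    list(a = unname(start[1]), b = unname(start[2])),
    list(a = a_exp, b = 0)  # nested-model start guarantees SSres <= exponential's
  )
  best <- NULL
  last_error <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(prop ~ exp(-a * n - b * n^2), data = dat, start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(f, "error")) { last_error <- f; next }
    if (is.null(best) || deviance(f) < deviance(best)) best <- f
  }
  if (is.null(best))
    stop("hyper-exponential fit did not converge: ", conditionMessage(last_error))

  co <- coef(best)
  if (errors == "binomial") {
    # iteratively reweight with the known binomial variance, then take the
    # absolute-sigma covariance (no residual-scale estimate)
    for (it in 1:2) {
      p_hat <- pmin(pmax(exp(-co[["a"]] * dat$n - co[["b"]] * dat$n^2), 1e-9), 1)
      v <- pmax(p_hat * (1 - p_hat) / dat$assayed, 1e-12)
      wfit <- tryCatch(
        minpack.lm::nlsLM(prop ~ exp(-a * n - b * n^2), data = dat,
                          start = as.list(co), weights = 1 / v,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(wfit)) break
      co <- coef(wfit)
    }
    p_hat <- pmin(pmax(exp(-co[["a"]] * dat$n - co[["b"]] * dat$n^2), 1e-9), 1)
    v <- pmax(p_hat * (1 - p_hat) / dat$assayed, 1e-12)
    J <- cbind(-dat$n * p_hat, -dat$n^2 * p_hat)
    cv <- tryCatch(solve(t(J) %*% (J / v)), error = function(e) matrix(NA_real_, 2, 2))
    se <- sqrt(diag(cv))
    names(se) <- c("a", "b")
  } else {
    se <- tryCatch(sqrt(diag(vcov(best))),
                   error = function(e) c(a = NA_real_, b = NA_real_))
  }
  out <- hyperexp_fit(
    alpha = co[["a"]], beta = co[["b"]],
    sigma_alpha = unname(se[1]), sigma_beta = unname(se[2]),
    r2_hyper = r_squared(dat$prop, fitted(best)),
    r2_exp = r_squared(dat$prop, fitted(fit_exp)),
    epistasis_k = epistasis_k
  )
  out$n_used <- dat$n
  out$errors <- errors
  out
}

#' Model ratio of successive survival probabilities
#'
#' `P(n + 1) / P(n) = exp(-alpha - beta * (2 n + 1))` under the
#' hyper-exponential model: the probability that one additional mutation
#' is tolerated by a protein already carrying `n`. This is the model-based
#' estimate of the tolerated-mutation fraction Ptol at reference depth
#' `n`. A ratio at or above 1 means no negative-epistasis regime at that
#' `n`; a warning is raised and the value returned as-is.
#'
#' @param fit A [hyperexp_fit()].
#' @param n Non-negative integer vector.
#' @return Numeric vector of ratios.
#' @examples
#' tolerated_ratio(hyperexp_fit(0.104, 0.019), 14)   # ~ 1/2
#' tolerated_ratio(hyperexp_fit(-0.047, 0.054), 10)  # ~ 1/3
#' @export
tolerated_ratio <- function(fit, n) {
  fit <- as_hyperexp_fit(fit)
  if (any(n < 0)) stop("n must be >= 0")
  r <- exp(-fit$alpha - fit$beta * (2 * n + 1))
  if (any(r >= 1))
    warning("tolerated ratio >= 1: the model shows no negative-epistasis decline at this n")
  r
}

#' Find the reference depth where the tolerated fraction reaches a target
#'
#' Scans `n = 0, 1, ..., n_max` for the first place the decreasing model
#' ratio `P(n+1)/P(n)` crosses `target_ptol`, and returns whichever of the
#' two bracketing depths has the smaller absolute deviation from the
#' target. This is the model-ratio reading of "the n where the tolerated
#' fraction first approximates" a benchmark value such as 1/3.
#'
#' @param fit A [hyperexp_fit()] with `beta > 0` (the ratio must decrease).
#' @param target_ptol Target tolerated fraction in (0, 1).
#' @param n_max Upper end of the scan range.
#' @return The selected integer depth `n0`.
#' @examples
#' select_reference_n(hyperexp_fit(0.096, 0.039), 1 / 3, n_max = 50)  # 12
#' @export
select_reference_n <- function(fit, target_ptol, n_max = 100L) {
  fit <- as_hyperexp_fit(fit)
  if (fit$beta <= 0) stop("select_reference_n requires beta > 0")
  if (target_ptol <= 0 || target_ptol >= 1) stop("target_ptol must be in (0, 1)")
  n <- 0:n_max
  ratio <- exp(-fit$alpha - fit$beta * (2 * n + 1))
  dev <- ratio - target_ptol
  hit <- which(dev == 0)
  if (length(hit)) return(n[hit[1]])
  cross <- which(dev[-length(dev)] > 0 & dev[-1] < 0)
  if (length(cross)) {
    i <- cross[1]
    return(if (abs(dev[i]) <= abs(dev[i + 1])) n[i] else n[i + 1])
  }
  if (min(abs(dev)) <= 0.1) return(n[which.min(abs(dev))])
  stop("no n in [0, ", n_max, "] brings the tolerated ratio within 0.1 of ",
       signif(target_ptol, 4))
}

#' @export
print.hyperexp_fit <- function(x, ...) {
  cat("Hyper-exponential mutational response P(n) = exp(-alpha n - beta n^2)\n")
  cat(sprintf("  alpha = %.4g", x$alpha))
  if (!is.na(x$sigma_alpha)) cat(sprintf(" (sd %.2g)", x$sigma_alpha))
  cat(sprintf("\n  beta  = %.4g", x$beta))
  if (!is.na(x$sigma_beta)) cat(sprintf(" (sd %.2g)", x$sigma_beta))
  cat("\n")
  if (!is.na(x$r2_hyper))
    cat(sprintf("  R^2: hyper-exponential %.4f, exponential %.4f\n", x$r2_hyper, x$r2_exp))
  if (!is.na(x$epistatic))
    cat("  epistatic (beta >= ", x$epistasis_k, " sigma_beta): ", x$epistatic, "\n", sep = "")
  invisible(x)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Mutational survival curve (", nrow(x), " points, n = ",
      min(x$n), "..", max(x$n), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
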