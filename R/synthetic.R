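# Seeded generators for mutational-survival curves and ddG samples with
# known ground truth, emulating the data shapes of mutational drift
# experiments and stability-database exports.

# fixed per-generator stream ids for seed derivation
STREAM_SURVIVAL <- 1L
STREAM_DDG <- 2L

#' Design of a synthetic mutational-survival experiment
#'
#' Ground-truth parameters for [simulate_survival_curve()]: the true
#' hyper-exponential parameters, the range of substitution counts assayed,
#' and how many clones are scored per count (a fixed number, or a Poisson
#' draw per round when emulating drift experiments where clone numbers
#' vary).
#'
#' @param alpha,beta True model parameters.
#' @param n_range Integer vector of substitution counts (e.g. `0:14`).
#' @param clones_per_n Clones assayed at each `n` (>= 1), or `NULL` to use
#'   `lambda`.
#' @param lambda Optional Poisson rate for per-`n` clone counts (drift
#'   mode); at least one clone is always assayed.
#' @param seed Integer seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(alpha, beta, n_range = 0:14,
                              clones_per_n = 1000, lambda = NULL, seed = 1L) {
  n_range <- as.integer(n_range)
  if (any(n_range < 0)) stop("n_range must be non-negative")
  if (is.null(clones_per_n) && is.null(lambda))
    stop("supply clones_per_n or lambda")
  if (!is.null(clones_per_n) && clones_per_n < 1)
    stop("clones_per_n must be >= 1")
  structure(list(alpha = alpha, beta = beta, n_range = n_range,
                 clones_per_n = clones_per_n, lambda = lambda,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a mutational-survival curve
#'
#' For each substitution count `n` in the design, draws the number of
#' functional clones as `Binomial(clones, P(n))` with
#' `P(n) = exp(-alpha n - beta n^2)`. Seeded and reproducible; the
#' caller's RNG state is left untouched.
#'
#' @param design A [simulation_design()].
#' @return A [survival_curve()] with counts.
#' @examples
#' d <- simulation_design(0.104, 0.019, n_range = 0:14, clones_per_n = 500,
#'                        seed = 42)
#' simulate_survival_curve(d)
#' @export
simulate_survival_curve <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_local_seed(derive_seed(design$seed, STREAM_SURVIVAL), {
    n <- design$n_range
    clones <- if (!is.null(design$clones_per_n)) {
      rep(design$clones_per_n, length(n))
    } else {
      pmax(1L, stats::rpois(length(n), design$lambda))
    }
    p <- exp(-design$alpha * n - design$beta * n^2)
    functional <- stats::rbinom(length(n), clones, pmin(p, 1))
    survival_curve(n = n, assayed = clones, functional = functional)
  })
}

#' Simulate ddG records from a mixture model
#'
#' Draws `n` stability changes from a [bigaussian()] (component chosen
#' Bernoulli(`w`), then the component Gaussian), returning a
#' [ddg_table()]. Seeded and reproducible.
#'
#' @param model A [bigaussian()].
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param protein Protein identifier for the records.
#' @return A [ddg_table()], with attribute `model` echoing the truth.
#' @export
simulate_ddg_sample <- function(model, n, seed = 1L, protein = "synthetic") {
  stopifnot(inherits(model, "bigaussian"), n >= 1)
  with_local_seed(derive_seed(seed, STREAM_DDG), {
    comp1 <- stats::runif(n) < model$w
    x <- ifelse(comp1,
                stats::rnorm(n, model$mu1, model$s1),
                stats::rnorm(n, model$mu2, model$s2))
    out <- ddg_table(protein = rep(protein, n), ddg = x)
    attr(out, "model") <- model
    out
  })
}

#' Synthetic study profiles
#'
#' Three named simulation designs whose true parameters mirror the fitted
#' hyper-exponential parameter sets of well-studied proteins (a
#' beta-lactamase-like, a GFP-like, and a HisA-like response). These are
#' synthetic test profiles, not experimental data.
#'
#' @param clones_per_n Clones per substitution count.
#' @param seed Base seed (each profile offsets it).
#' @return Named list of [simulation_design()]s with an `L` attribute on
#'   each.
#' @export
synthetic_profiles <- function(clones_per_n = 1000, seed = 1L) {
  mk <- function(alpha, beta, n_max, L, off) {
    d <- simulation_design(alpha, beta, n_range = 0:n_max,
                           clones_per_n = clones_per_n, seed = seed + off)
    attr(d, "L") <- as.integer(L)
    d
  }
  list(
    beta_lactamase_like = mk(0.104, 0.019, 14, 263, 0L),
    gfp_like = mk(-0.047, 0.054, 10, 238, 100L),
    hisa_like = mk(0.096, 0.039, 7, 254, 200L)
  )
}
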