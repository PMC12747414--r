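---
title: "Estimating protein rarity from mutational tolerance and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein rarity from mutational tolerance and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismr)
```

## The question and the model

Protein rarity asks what fraction of amino acid sequence space corresponds
to sequences that fold and perform a given function (Pfs). Direct
measurement is only possible for low-specificity activities such as simple
binding; for enzymes and other high-specificity proteins, rarity must be
inferred from how accumulating mutations degrade stability and function.

The core observable is the mutational-survival curve P(n): the proportion
of clones that remain functional after n nonsynonymous substitutions.
Because most mutations destabilize, and because accumulated mutations make
each additional one more likely to push the protein past its stability
threshold (negative epistasis), P(n) falls faster than exponentially. We
model it as

$$P(n) = e^{-\alpha n - \beta n^2},$$

where α is the initial per-substitution decline and β the acceleration
attributable to negative epistasis. A significantly positive β (default
criterion β ≥ 2σ~β~, configurable through `epistasis_k`) is what licenses
the target-based machinery below: it implies essentially all functional
sequences lie within a bounded neighbourhood of the wildtype.

`fit_response()` fits this model by unweighted nonlinear least squares on
the linear proportion scale (Levenberg–Marquardt via minpack.lm), together
with the nested exponential (β = 0) for comparison. Both parameters are
unconstrained; negative fitted α occurs in real data when single mutants
slightly outperform the model's n = 0 anchor. R² is computed against the
mean of the included proportions for both models; since the exponential is
the nested special case, r2_hyper ≥ r2_exp for any converged fit (the
fitter seeds one of its starts at the exponential solution to make this
robust even on degenerate, zero-residual curves).

### Parameter errors: two modes

The default (`errors = "estimated"`) takes σ~α~, σ~β~ from the usual fit
covariance, which scales by the pooled residual variance. With the ~10–15
points a typical drift experiment provides, a "3σ" criterion under an
estimated scale is effectively a t-test on few degrees of freedom, and the
nominal 3σ coverage of ~99.7% per parameter erodes to ~97–98%. When the
curve carries clone counts, the sampling variance p(1−p)/N is *known*, so
`errors = "binomial"` reweights the fit with it and reports the
absolute-sigma covariance (Jᵀ V⁻¹ J)⁻¹ with no estimated scale. In
simulation this restores calibrated coverage (≥99% of replicates within
3σ jointly); it is the mode the package's own recovery tests use, and the
recommended one whenever counts are available.

## From tolerance to a target boundary

Once a protein has drifted past its stability threshold, each new mutation
is tolerated with some probability Ptol. Three readings of Ptol are
supported:

- a measured plateau from drift experiments with selection between rounds;
- the model ratio `tolerated_ratio()` = P(n+1)/P(n) = e^{−α−β(2n+1)} at a
  reference depth n₀, with `select_reference_n()` locating the first depth
  where the decreasing ratio crosses a benchmark value (the scan returns
  whichever of the two bracketing depths deviates least — the tie-break is
  not canonical, so it is documented and configurable by overriding n₀);
- a benchmark transfer: β-lactamase's measured Ptol = 1/3 is packaged as
  the default benchmark for proteins whose function is at least as
  demanding.

The survival bound drops below the discoverability floor P~min~ after
`boundary_from_tolerance()`

$$n_b = \frac{\log(P_{min}/P(n_0))}{\log(P_{tol})} + n_0$$

further substitutions (rounded to nearest by default; floor/ceiling
offered). P~min~ defaults to Pth = 1e-40, the reciprocal of the ~1e38
distinct gene variants that could ever have been trialled on Earth; a
1e-20 preset (`search_constants_eukaryote()`) reflects the much smaller
search resources of multicellular eukaryote lineages.

The raw n~b~ is then widened to a calibrated target for conservatism:
to the c = 1/3 boundary (ca = 0.57, the ~40% sequence-identity level below
which shared function becomes unlikely) when n~b~ falls inside it,
otherwise to c = 1/2 (ca = 0.77, shared structure). Above both, n~b~ is
used directly with a warning, capped at L. The ca constants are adopted
calibration inputs, not derived here. Published conversions of ca·L to an
integer are not internally consistent (0.57·263 is printed as 150 where
floor gives 149, while 0.57·238 → 135 and 0.57·254 → 144 are floors);
`target_from_fraction()` defaults to floor and exposes `rounding =
"round"`, which the β-lactamase worked example requires.

## Sequence-space combinatorics

The number of sequences at Hamming distance n from a length-L reference is
C(L, n)·19ⁿ. `prob_in_target()` computes

$$P_t = \frac{\sum_{n=0}^{n_b} \binom{L}{n} 19^n}{20^L}$$

in two independent ways: an exact summation in arbitrary-precision
integers (a small base-10⁴ bignum arithmetic implemented in the package,
taking one logarithm at the end) and a log-sum-exp evaluation in double
precision. The two agree to better than 1e-9 across all tested lengths up
to 400; the exact route is the default and the dual evaluation is kept as
a standing cross-check. All probabilities are carried as log10 reals
throughout the package — nothing ever underflows.

`functional_density()` combines the two opposing trends — P(n) falling
ever faster, Nseq(n) rising ever slower — into PDF(n), the distribution of
functional sequences over Hamming distance, normalised by log-sum-exp over
n = 0..L. Because β is only measured at small n and is known to change at
large n, the density is quantitatively trustworthy only near its mode; it
is intended for qualitative comparison between proteins (the FSH radial
map, `fsh_map_data()` / `plot()`), and the output carries the full
log-weights so users can judge the tail themselves.

## Rarity estimators

Four estimators cover the evidence spectrum (`route_method()` walks the
decision tree):

1. **Direct library screening** for low-specificity functions — advisory
   routing only; no computation.
2. **Target-based composite** (`run_epistatic_pipeline()`):
   Pubt = Ptol^{n_b} bounds the functional fraction inside the target, and
   Pub = Pt·Pubt bounds it globally.
3. **Whole-length tolerance bound**: Pub = Ptol^L when no target can be
   defined. Always weaker than the composite, since it pretends the
   outside of the target is as dense as the inside. Its inverse
   (`tolerance_from_rarity()`) turns external rarity estimates into
   effective per-position tolerances for cross-study comparison.
4. **Stability proxy**: Pub = Pnd^L, with Pnd the fraction of mutations
   whose ΔΔG falls below a cutoff G~th~ — destabilizing and deleterious
   mutations are tightly correlated for globular proteins.

Exponent reporting follows two conventions because published tables use
both: round-to-nearest log10 for the target pipeline and
scientific-notation floor for the Pnd^L tables. `format_exponent()` makes
the choice explicit, the composite's formatted exponent is the sum of the
individually formatted component exponents (matching how
order-of-magnitude chains are quoted), and every report carries the raw
log10 value alongside. The published short-domain whole-length table
cannot be reproduced under any single convention (its implied n~b~
rounding conflicts with the worked β-lactamase chain), so no attempt is
made; the raw values are authoritative.

## Discovery times

For evolutionary-scenario questions the in-target probability converts to
an expected discovery time d = A·B^L for an undirected search, with
adopted constants A = 2.21, B = 3.25 (c = 1/3) and A = 5.36, B = 1.56
(c = 1/2). The c = 1/2 coefficient is printed inconsistently at its source
(5.39 in one place, 5.36 in the equation); 5.36 is used — the two give
identical rounded exponents in every worked case. Two published discovery
times (the 263-residue c = 1/3 case printed as 10^133 and the 254-residue
c = 1/2 case printed as 10^48) are not reproducible from these constants
at the stated lengths and are treated as source-side inconsistencies; the
package reports what the constants give.

`discovery_probability()` evaluates Pdt = 1 − e^{−Tm/d} stably: the ratio
is formed in log10, `-expm1(-x)` covers the ordinary range, and a
first-order series with a `log1p` correction covers Tm/d < 1e-8 where the
direct expression would cancel catastrophically.

With m equivalent targets the expected time is dm = (1/m)·e^{6L(3/4−c)²},
and inverting for a trial budget gives the smallest discoverable target
`minimum_discoverable_target()` — insensitive to m (a 10¹⁰-fold increase
in targets moves cmin by ~3 points at L = 250), which is why single-target
estimates are considered robust. Percent outputs are rounded to whole
percent, matching how these quantities are quoted.

## ΔΔG distributions

Empirical ΔΔG distributions are modelled as two-component Gaussian
mixtures (`bigaussian()`; sign convention: positive destabilizes).
`calibrate_threshold()` inverts the mixture CDF by bracketing root-finding
(tolerance 1e-9 kcal/mol) to find the cutoff G~th~ at which the integrated
density equals a benchmark Ptol — applied to a β-lactamase-style mixture
at Ptol = 1/3 this lands near 0.5 kcal/mol, the field's customary cutoff,
with 1.0 kcal/mol as the conservative alternative.

`nondestabilizing_fraction_empirical()` computes per-protein Pnd from
record tables as the fraction of entries *strictly* below the cutoff (ties
count as destabilizing — the convention is not settled in the literature,
so it is documented and the cutoff side is explicit). Proteins with fewer
than 30 records are excluded by default: with p ≈ 0.4, thirty records
still leave a ±0.09 standard error on Pnd, and fewer records make the
derived Pnd^L bound meaningless. Duplicate measurements of the same
mutation count separately by default (`dedup = TRUE` averages them), since
repository entries, not unique mutations, are the raw evidence.

## The synthetic-data generator

`simulate_survival_curve()` draws functional counts as
Binomial(clones, P(n)) per depth — the data shape of a drift experiment
without selection between rounds — and `simulate_ddg_sample()` draws from
a mixture. Defaults are chosen to mirror the study conditions of the
well-characterised proteins: the three named profiles in
`synthetic_profiles()` carry the published fitted parameter pairs
(α = 0.104, β = 0.019; α = −0.047, β = 0.054; α = 0.096, β = 0.039) with
their lengths, and 1000 clones per depth is the order of a deep
mutagenesis round. One user seed expands into fixed per-generator streams,
so adding a generator never perturbs existing draws, and the caller's RNG
state is restored afterwards.

What the generator does *not* emulate: selection between rounds (Ptol
plateaus are consumed as scalars, never simulated), sequencing error,
overdispersion beyond binomial, correlated mutations at the sequence
level, or the drift of β with large n. Passing recovery tests therefore
show that the estimators are correct *under the model*, not that the model
captures every feature of real drift data.

## Numerical choices and problem sizes

- All probability arithmetic in log10; exact integer arithmetic for counts
  and Pt sums; the exact-vs-log cross-check is asserted at 1e-9.
- Fit initial guess (0.1, 0.01) — the order of magnitude of all published
  fits; a second start at the exponential solution guards the nested-model
  invariant.
- Zero-proportion points are retained in fits by default (they inform the
  tail); `drop_zeros` removes them.
- The test suite exercises recovery on 200 seeded replicates at 500–1000
  clones per depth and n = 0..10 (a few seconds), empirical-Pnd
  convergence at 1e5 draws, and brute-force enumeration oracles at L = 4
  for the combinatorics; the exact Pt summation at L = 263 runs in
  milliseconds.

## Limitations

- All rarity outputs are *upper bounds*; the true Pfs can be far smaller
  (the functional-density mode for the 263-residue worked case sits at
  ca ≈ 0.35, well inside the c = 1/3 target used for the bound).
- The hyper-exponential extrapolation beyond measured n is qualitative;
  FSH maps should be compared, not read quantitatively.
- The ΔΔG proxy assumes globular-protein stability constraints; it is not
  expected to hold for intrinsically disordered or low-complexity regions,
  where deleterious and destabilizing mutations decouple.
- Functional specificity is a user judgment recorded with a justification
  string, never inferred from sequence.
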