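test_that("sequence counts match brute-force enumeration over a 20-letter alphabet", {
  # enumerate every length-4 sequence and tabulate Hamming distance from a
  # fixed reference
  L <- 4
  idx <- as.matrix(expand.grid(rep(list(1:20), L)))
  dist <- rowSums(idx != 1L)
  brute <- tabulate(dist + 1L, nbins = L + 1L)
  for (n in 0:L) {
    expect_identical(as.character(count_sequences_at_distance(L, n)),
                     format(brute[n + 1L], scientific = FALSE))
  }
})

test_that("sequence count edge cases and the frozen small case hold", {
  expect_identical(as.character(count_sequences_at_distance(17, 0)), "1")
  expect_identical(as.character(count_sequences_at_distance(1, 1)), "19")
  expect_identical(as.character(count_sequences_at_distance(5, 2)), "3610")
  expect_error(count_sequences_at_distance(5, 6), "\\[0, L\\]")
  expect_error(count_sequences_at_distance(5, -1), "\\[0, L\\]")
})

test_that("counts over all distances sum exactly to 20^L (binomial theorem)", {
  for (L in c(1, 7, 18, 30)) {
    total <- prismr:::big_from_int(0)
    for (n in 0:L) total <- prismr:::big_add(total, count_sequences_at_distance(L, n))
    expect_true(prismr:::big_eq(total, prismr:::big_pow_small(20, L)))
  }
})

test_that("exact and log-sum-exp in-target probabilities agree to 1e-9", {
  grid <- expand.grid(L = c(50, 150, 263, 400), frac = c(0.1, 0.5, 0.57, 0.9))
  for (i in seq_len(nrow(grid))) {
    L <- grid$L[i]
    nb <- floor(grid$frac[i] * L)
    expect_equal(prob_in_target(L, nb, "exact"), prob_in_target(L, nb, "log"),
                 tolerance = 1e-9)
  }
})

test_that("in-target probability is nondecreasing in nb and complete at nb = L", {
  L <- 80
  vals <- vapply(seq(0, L, by = 8), function(nb) prob_in_target(L, nb), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_identical(prob_in_target(L, L), 0)
  expect_identical(prob_in_target(263, 263), 0)
  # direct small-case arithmetic: 1 + 3*19 = 58 sequences of 20^3
  expect_equal(prob_in_target(3, 1), log10(58 / 8000), tolerance = 1e-12)
})

test_that("functional density normalises and peaks in the published ranges", {
  cases <- list(
    list(fit = fit_bla, L = 263, lo = 80, hi = 105),
    list(fit = fit_gfp, L = 238, lo = 30, hi = 50),
    list(fit = fit_hisa, L = 254, lo = 40, hi = 60)
  )
  for (cs in cases) {
    d <- functional_density(cs$fit, cs$L)
    expect_equal(sum(d$pdf), 1, tolerance = 1e-9)
    expect_identical(d$n, 0:cs$L)
    mode <- d$n[which.max(d$pdf)]
    expect_gte(mode, cs$lo)
    expect_lte(mode, cs$hi)
  }
})

test_that("with all sequences functional the density is the sequence-count distribution", {
  L <- 10
  d <- functional_density(hyperexp_fit(0, 0), L)
  counts <- choose(L, 0:L) * 19^(0:L)
  expect_equal(d$pdf, counts / sum(counts), tolerance = 1e-12)
})

test_that("target fractions map to the published boundaries", {
  expect_identical(target_from_fraction(c = 1 / 3, L = 238)$nb, 135L)
  expect_identical(target_from_fraction(c = 1 / 3, L = 254)$nb, 144L)
  expect_identical(target_from_fraction(c = 1 / 3, L = 263, rounding = "round")$nb, 150L)
  expect_identical(target_from_fraction(ca = 1.0, L = 77)$nb, 77L)
  expect_identical(target_from_fraction(c = 1 / 2, L = 263)$nb, 202L)
  expect_error(target_from_fraction(c = 0.4, L = 100), "supply ca")
})

test_that("FSH map data carries density rows and boundary radii", {
  d <- functional_density(fit_bla, 263)
  b13 <- target_from_fraction(c = 1 / 3, L = 263, rounding = "round")
  tab <- fsh_map_data(d, list(b13))
  expect_identical(attr(tab, "boundaries")$radius, 150)
  # essentially all functional-sequence mass lies inside the c = 1/3 ring
  expect_true(all(tab$pdf[tab$n > 150] < 1e-6))
  # no boundaries -> empty sidecar
  expect_identical(nrow(attr(fsh_map_data(d), "boundaries")), 0L)
  # a single nonzero pdf shows up as a single ring
  one <- d
  one$pdf <- as.numeric(one$n == 42)
  rings <- fsh_map_data(one)
  expect_identical(rings$n[rings$pdf > 0], 42L)
})
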