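test_that("mixture cdf has the expected symmetries and limits", {
  expect_equal(mixture_cdf(bigaussian(1, 0, 1), 0), 0.5)
  expect_equal(mixture_cdf(bigaussian(0.5, -1, 0.5, 1, 0.5), 0), 0.5)
  expect_equal(mixture_cdf(mix_test, 1e6), 1)
  expect_equal(mixture_cdf(mix_test, -1e6), 0)
  x <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(mixture_cdf(mix_test, x)) >= 0))
  # density integrates to 1
  expect_equal(stats::integrate(function(x) mixture_pdf(mix_test, x),
                                -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("threshold calibration inverts the mixture cdf", {
  expect_equal(calibrate_threshold(bigaussian(1, 0, 1), 0.5), 0, tolerance = 1e-6)
  # inverse round-trip through an off-centre point
  p <- mixture_cdf(mix_test, 0.5)
  expect_equal(calibrate_threshold(mix_test, p), 0.5, tolerance = 1e-5)
  # dense-grid numeric inversion as an independent oracle
  grid <- seq(-3, 3, by = 1e-5)
  cdf_grid <- mixture_cdf(mix_test, grid)
  oracle <- grid[which.max(cdf_grid >= 1 / 3)]
  expect_lt(abs(calibrate_threshold(mix_test, 1 / 3) - oracle), 1e-4)
  # round-trip accuracy across quantiles
  for (p in c(0.05, 1 / 3, 0.5, 0.9)) {
    expect_equal(mixture_cdf(mix_test, calibrate_threshold(mix_test, p)), p,
                 tolerance = 1e-7)
  }
})

test_that("model non-destabilizing fraction matches quadrature", {
  expect_equal(nondestabilizing_fraction_model(bigaussian(1, 0.5, 1), 0.5), 0.5)
  q <- stats::integrate(function(x) mixture_pdf(mix_test, x), -Inf, 0.5,
                        rel.tol = 1e-10)$value
  expect_equal(nondestabilizing_fraction_model(mix_test, 0.5), q, tolerance = 1e-6)
  # the conservative cutoff always admits at least as many mutations
  models <- list(mix_test, bigaussian(0.7, 0.2, 0.4, 2.5, 1.5), bigaussian(1, 1, 2))
  for (m in models) {
    expect_gte(nondestabilizing_fraction_model(m, 1.0),
               nondestabilizing_fraction_model(m, 0.5))
  }
})

test_that("empirical fractions count strictly below the cutoff, per protein", {
  tab <- ddg_table(rep("p", 4), c(-1, 0, 1, 2))
  fr <- nondestabilizing_fraction_empirical(tab, g_th = 0.5, min_records = 1)
  expect_equal(fr$pnd, 0.5)
  # ties at the cutoff count as destabilizing
  tie <- ddg_table(rep("p", 2), c(0.5, 0.4))
  expect_equal(nondestabilizing_fraction_empirical(tie, 0.5, min_records = 1)$pnd, 0.5)
})

test_that("the record filter excludes under-sampled proteins", {
  tab <- ddg_table(c(rep("few", 29), rep("enough", 30)),
                   c(rnorm(29), rnorm(30)))
  fr <- nondestabilizing_fraction_empirical(tab, min_records = 30)
  expect_identical(fr$protein, "enough")
  expect_identical(attr(fr, "excluded"), "few")
  all_few <- ddg_table(rep(c("a", "b"), each = 29), rnorm(58))
  fr2 <- nondestabilizing_fraction_empirical(all_few, min_records = 30)
  expect_identical(nrow(fr2), 0L)
  expect_setequal(attr(fr2, "excluded"), c("a", "b"))
  expect_warning(nondestabilizing_fraction_empirical(
    ddg_table(character(0), numeric(0))), "empty")
})

test_that("empirical fractions converge to the mixture cdf on simulated data", {
  n <- 1e5
  tab <- simulate_ddg_sample(mix_test, n, seed = 99)
  for (g in c(0.5, 1.0)) {
    p <- nondestabilizing_fraction_model(mix_test, g)
    fr <- nondestabilizing_fraction_empirical(tab, g_th = g, min_records = 30)
    expect_lt(abs(fr$pnd - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("deduplication averages repeated mutation records", {
  tab <- ddg_table(rep("p", 40),
                   ddg = c(rep(c(0.2, 0.8), 10), rnorm(20, 2)),
                   position = c(rep(1L, 20), 2:21),
                   wt = rep("A", 40), mut = rep("G", 40))
  raw <- nondestabilizing_fraction_empirical(tab, 0.5, min_records = 1)
  dd <- nondestabilizing_fraction_empirical(tab, 0.5, min_records = 1, dedup = TRUE)
  # duplicates at position 1 average to 0.5, which is not below the cutoff
  expect_gt(raw$pnd, dd$pnd)
})

test_that("the rarity summary combines cutoffs, lengths, and thresholds", {
  tab <- simulate_ddg_sample(mix_test, 500, seed = 3, protein = "synthA")
  summ <- ddg_rarity_summary(tab, lengths = c(synthA = 263))
  expect_identical(nrow(summ), 2L)
  expect_true(all(summ$g_th == c(0.5, 1.0)))
  expect_true(all(summ$log10_pub < 0))
  expect_identical(summ$exponent_floor, format_exponent(summ$log10_pub, "floor"))
})
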