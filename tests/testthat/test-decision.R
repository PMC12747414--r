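test_that("routing covers every valid evidence combination exactly once", {
  fit_epi <- hyperexp_fit(0.104, 0.019, sigma_beta = 0.004)   # clearly epistatic
  fit_flat <- hyperexp_fit(0.3, 0.001, sigma_beta = 0.01)     # beta not significant
  mix <- bigaussian(1, 1, 1)

  expect_identical(route_method(evidence_profile("low", L = 50))$method,
                   "direct_library")
  expect_identical(
    route_method(evidence_profile("high", L = 263, fit = fit_epi))$method,
    "epistatic_target")
  # non-epistatic P(n) falls through to the tolerance bound
  expect_identical(
    route_method(evidence_profile("high", L = 263, fit = fit_flat, ptol = 0.5))$method,
    "ptol_only")
  expect_identical(
    route_method(evidence_profile("high", L = 100, ptol = 0.4))$method,
    "ptol_only")
  expect_identical(
    route_method(evidence_profile("high", L = 100, ddg = mix))$method,
    "ddg_proxy")
  # epistasis asserted directly, without a fit
  cv <- survival_curve(0:3, prop = c(1, 0.8, 0.5, 0.2))
  expect_identical(
    route_method(evidence_profile("high", L = 50, curve = cv,
                                  epistatic = TRUE))$method,
    "epistatic_target")
  expect_error(route_method(evidence_profile("high", L = 100)), "unroutable")
  expect_error(evidence_profile("high", L = 100, epistatic = TRUE),
               "only meaningful")
})

test_that("the epistatic pipeline reproduces the beta-lactamase chain", {
  profile <- evidence_profile("high", L = 263,
                              fit = hyperexp_fit(0.104, 0.019, sigma_beta = 0.004),
                              ptol = 1 / 3)
  run <- run_epistatic_pipeline(profile, n0 = 7, p_n0 = 0.19,
                                nb_rounding = "round")
  expect_identical(run$target$nb_raw, 89L)
  expect_identical(run$target$clamped_to, "c=1/3")
  expect_identical(run$target$nb_used, 150L)
  expect_identical(run$report$exponents$pt, -74L)
  expect_identical(run$report$exponents$pubt, -72L)
  expect_identical(run$report$exponents$pub, -146L)
})

test_that("the epistatic pipeline reproduces the GFP chain", {
  profile <- evidence_profile("high", L = 238,
                              fit = hyperexp_fit(-0.047, 0.054, sigma_beta = 0.001),
                              ptol = 1 / 3)
  run <- run_epistatic_pipeline(profile, n0 = 10, p_n0 = 0.007)
  expect_identical(run$target$nb_raw, 89L)
  expect_identical(run$target$nb_used, 135L)
  expect_identical(run$report$exponents$pt, -68L)
  expect_identical(run$report$exponents$pubt, -64L)
  expect_identical(run$report$exponents$pub, -132L)
  expect_identical(format_exponent(run$discovery$log10_d, "round"), 122L)
  expect_identical(format_exponent(run$discovery$log10_pdt, "round"), -84L)
})

test_that("clamping only ever widens the target", {
  profile <- evidence_profile("high", L = 263,
                              fit = hyperexp_fit(0.104, 0.019, sigma_beta = 0.004),
                              ptol = 1 / 3)
  for (p_n0 in c(0.5, 0.19, 0.05)) {
    run <- run_epistatic_pipeline(profile, n0 = 7, p_n0 = p_n0)
    expect_gte(run$target$nb_used, run$target$nb_raw)
  }
  # boundary above c = 1/2: warning, nb used directly
  expect_warning(
    run <- run_epistatic_pipeline(profile, n0 = 7, p_n0 = 0.19, ptol = 0.65),
    "c = 1/2")
  expect_identical(run$target$clamped_to, "none")
  expect_identical(run$target$nb_used, run$target$nb_raw)
  # a very weak tolerance pushes the formula past L; the boundary caps there
  expect_warning(
    capped <- run_epistatic_pipeline(profile, n0 = 7, p_n0 = 0.19, ptol = 0.9),
    "c = 1/2")
  expect_identical(capped$target$clamped_to, "L")
  expect_identical(capped$target$nb_used, 263L)
})

test_that("the pipeline is deterministic and self-consistent at the boundary", {
  profile <- evidence_profile("high", L = 254,
                              fit = hyperexp_fit(0.096, 0.039, sigma_beta = 0.013),
                              ptol = 1 / 3)
  r1 <- run_epistatic_pipeline(profile)
  r2 <- run_epistatic_pipeline(profile)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$inputs$n0, 12L)  # model-ratio reading of the reference depth
  expect_identical(r1$target$nb_raw, 90L)
  # composite identity on the raw scale
  expect_equal(r1$report$log10_pub, r1$report$log10_pt + r1$report$log10_pubt)
})
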