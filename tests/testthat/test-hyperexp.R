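test_that("survival_curve validates its invariants", {
  expect_s3_class(survival_curve(0:2, prop = c(1, 0.5, 0.2)), "survival_curve")
  expect_error(survival_curve(c(0, 2, 1), prop = c(1, 0.5, 0.2)), "increasing")
  expect_error(survival_curve(0:1, prop = c(1, 1.2)), "\\[0, 1\\]")
  expect_error(survival_curve(0:1, assayed = c(10, 10), functional = c(10, 12)),
               "exceed")
  # counts define the proportion exactly
  cv <- survival_curve(0:2, assayed = c(8, 8, 8), functional = c(8, 4, 1))
  expect_identical(cv$prop, c(1, 0.5, 0.125))
})

test_that("the survival model evaluates to the published worked values", {
  expect_equal(round(eval_pn(fit_bla, 7), 2), 0.19)
  expect_equal(round(eval_pn(fit_gfp, 10), 3), 0.007)
  expect_identical(eval_pn(fit_bla, 0), 1)
  expect_identical(eval_pn(hyperexp_fit(2.3, -0.4), 0), 1)
})

test_that("survival decreases in n whenever alpha >= 0 and beta > 0", {
  grid <- expand.grid(alpha = c(0, 0.05, 0.2), beta = c(0.005, 0.05))
  for (i in seq_len(nrow(grid))) {
    p <- eval_pn(hyperexp_fit(grid$alpha[i], grid$beta[i]), 0:40)
    expect_true(all(diff(p) < 0))
  }
})

test_that("noiseless curves are recovered exactly", {
  cv <- noiseless_curve(fit_bla, 0:14)
  ft <- fit_response(cv)
  expect_equal(ft$alpha, 0.104, tolerance = 1e-6)
  expect_equal(ft$beta, 0.019, tolerance = 1e-6)
  expect_true(ft$r2_hyper > 0.999999)
})

test_that("a pure exponential curve yields beta ~ 0 and equal model fits", {
  cv <- survival_curve(0:12, prop = exp(-0.3 * (0:12)))
  ft <- fit_response(cv)
  expect_equal(ft$beta, 0, tolerance = 1e-6)
  expect_lt(ft$r2_hyper - ft$r2_exp, 1e-9)
  expect_gte(ft$r2_hyper, ft$r2_exp)
})

test_that("refitting a fitted model is idempotent", {
  cv <- simulate_survival_curve(simulation_design(0.09, 0.03, 0:12, 2000, seed = 11))
  f1 <- fit_response(cv)
  cv2 <- noiseless_curve(f1, cv$n)
  f2 <- fit_response(cv2)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-9)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
})

test_that("fit requires at least 3 usable points and honors max_n", {
  expect_error(fit_response(survival_curve(0:1, prop = c(1, 0.5))), "3")
  cv <- noiseless_curve(fit_bla, 0:14)
  expect_error(fit_response(cv, max_n = 1), "at least 3")
  ft <- fit_response(cv, max_n = 9)
  expect_setequal(ft$n_used, 0:9)
})

test_that("tolerated ratio matches the published approximations", {
  expect_identical(round(tolerated_ratio(fit_bla, 14), 3), 0.519)  # ~ 1/2
  expect_identical(round(tolerated_ratio(fit_gfp, 10), 3), 0.337)  # ~ 1/3
  # beta = 0 removes the n dependence
  r <- tolerated_ratio(hyperexp_fit(0.5, 0), c(0, 5, 50))
  expect_equal(r, rep(exp(-0.5), 3))
})

test_that("tolerated ratio is strictly decreasing when beta > 0 and warns otherwise", {
  r <- tolerated_ratio(fit_hisa, 0:30)
  expect_true(all(diff(r) < 0))
  expect_warning(tolerated_ratio(hyperexp_fit(-0.5, 0.01), 2), "no negative-epistasis")
})

test_that("reference depth selection finds the first crossing", {
  expect_identical(select_reference_n(fit_hisa, 1 / 3, n_max = 50), 12L)
  # analytically forced: ratio at n is exp(-0.05 (2n + 1)), equal to the
  # target exactly at n = 10
  expect_identical(select_reference_n(hyperexp_fit(0, 0.05), exp(-0.05 * 21),
                                      n_max = 40), 10L)
  expect_error(select_reference_n(hyperexp_fit(0.5, 0), 1 / 3), "beta > 0")
  # ratio never gets near the target inside the scan range
  expect_error(select_reference_n(hyperexp_fit(0, 1e-4), 1e-3, n_max = 5),
               "within 0.1")
})

test_that("binomial-noise recovery lands within 3 reported sigmas", {
  # 200 seeded replicates at 1000 clones per n; both parameters within
  # 3 sigma of truth in at least 99% of replicates. Clone counts are
  # known, so the calibrated known-variance errors apply.
  truth <- c(alpha = 0.054, beta = 0.03)
  ok <- logical(200)
  for (s in seq_len(200)) {
    cv <- simulate_survival_curve(
      simulation_design(truth["alpha"], truth["beta"], 0:10, 1000, seed = s))
    ft <- fit_response(cv, errors = "binomial")
    ok[s] <- abs(ft$alpha - truth["alpha"]) <= 3 * ft$sigma_alpha &&
      abs(ft$beta - truth["beta"]) <= 3 * ft$sigma_beta
  }
  expect_gte(mean(ok), 0.99)
})

test_that("binomial-error mode requires counts and reports its mode", {
  cv <- survival_curve(0:5, prop = eval_pn(fit_bla, 0:5))
  expect_error(fit_response(cv, errors = "binomial"), "counts")
  sim <- simulate_survival_curve(simulation_design(0.1, 0.02, 0:8, 500, seed = 3))
  ft <- fit_response(sim, errors = "binomial")
  expect_identical(ft$errors, "binomial")
  expect_gte(ft$r2_hyper, ft$r2_exp)
})
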