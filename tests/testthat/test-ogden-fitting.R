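test_that("objective E matches an independent loop oracle", {
  # hand cases
  p <- ogden_params(0.005, 10)
  # single point with a unit residual: E = 1/2
  expect_equal(objective_e(p, stress_strain_curve("h", 1.3,
                 uniaxial_nominal_stress(p, 1.3) + 1)), 0.5)
  # zero residual for a curve generated from the same parameters
  cv <- law_curve(p, n = 30)
  expect_lt(objective_e(p, cv), 1e-25)
  # random case vs naive loop
  set.seed(21)
  q <- rand_stable_params()
  cvr <- stress_strain_curve("r", seq(1, 1.5, length.out = 20),
                             runif(20, 0, 0.2))
  loop <- 0
  for (i in 1:20) {
    pred <- 0
    for (j in 1:q$n_terms)
      pred <- pred + 2 * q$mu[j] * (cvr$stretch[i]^(q$alpha[j] - 1) -
                                      cvr$stretch[i]^(-q$alpha[j] / 2 - 1))
    loop <- loop + 0.5 * (cvr$nominal_stress_mpa[i] - pred)^2
  }
  expect_lt(abs(objective_e(q, cvr) - loop), 1e-12)
})

test_that("fit configuration validates bounds and feasibility", {
  expect_error(fit_config(mu_lower = 0), "positive")
  expect_error(fit_config(mu_lower = 0.6, mu_upper = 0.5), "below")
  expect_error(fit_ogden(law_curve(ogden_params(0.005, 10), n = 3),
                         fit_config(n_terms = 2)), "at least")
  expect_error(fit_ogden(law_curve(ogden_params(0.005, 10), 1, 1.01, n = 20),
                         fit_config(n_terms = 2)), "range")
})

test_that("noiseless two-term curves are recovered to sub-0.1% stress RMSE", {
  truth <- ogden_params(mu = c(0.0029, 0.0584), alpha = c(0.2267, 14.055))
  cv <- law_curve(truth, 1.0, 1.6, n = 50, id = "row9")
  fr <- fit_ogden(cv, fit_config(rng_seed = 7))
  expect_lt(fr$rmse_mpa, 0.001 * max(cv$nominal_stress_mpa))
  expect_true(is_stable(fr$params))
  # bounds hold
  expect_true(all(fr$params$mu >= 1e-6 & fr$params$mu <= 0.5))
  expect_true(all(fr$params$alpha >= 1e-3 & fr$params$alpha <= 50))
  # terms reported in ascending alpha order
  expect_true(all(diff(fr$params$alpha) >= 0))
  # error_e and rmse are consistent
  expect_equal(fr$rmse_mpa, sqrt(2 * fr$error_e / fr$n_data))
})

test_that("one-term fits recover the generating constants within 1%", {
  truth <- ogden_params(0.005, 10)
  cv <- law_curve(truth, 1.0, 1.5, n = 50)
  fr <- fit_ogden(cv, fit_config(n_terms = 1, rng_seed = 3))
  expect_lt(abs(fr$params$mu - 0.005) / 0.005, 0.01)
  expect_lt(abs(fr$params$alpha - 10) / 10, 0.01)
  # independent brute-force grid-search oracle agrees
  gs <- grid_search_one_term(cv)
  expect_lt(abs(fr$params$mu - gs$mu) / gs$mu, 0.01)
  expect_lt(abs(fr$params$alpha - gs$alpha) / gs$alpha, 0.01)
})

test_that("fitting is deterministic and multistart-monotone", {
  set.seed(99)
  truth <- rand_stable_params()
  lam <- seq(1, 1.5, length.out = 40)
  noisy <- uniaxial_nominal_stress(truth, lam) +
    rnorm(40, 0, 0.02 * max(uniaxial_nominal_stress(truth, lam)))
  noisy[1] <- max(noisy[1], 0)
  cv <- stress_strain_curve("n", lam, noisy)
  a <- fit_ogden(cv, fit_config(rng_seed = 5, n_multistarts = 8))
  b <- fit_ogden(cv, fit_config(rng_seed = 5, n_multistarts = 8))
  expect_identical(a$params$mu, b$params$mu)
  expect_identical(a$params$alpha, b$params$alpha)
  expect_identical(a$error_e, b$error_e)
  # nested starts: more multistarts never worsen the objective
  e2 <- fit_ogden(cv, fit_config(rng_seed = 5, n_multistarts = 2))$error_e
  e8 <- a$error_e
  e16 <- fit_ogden(cv, fit_config(rng_seed = 5, n_multistarts = 16))$error_e
  expect_lte(e8, e2)
  expect_lte(e16, e8)
})

test_that("degenerate all-zero curves return a feasible near-zero fit", {
  cv <- stress_strain_curve("flat", seq(1, 1.3, length.out = 20), rep(0, 20))
  fr <- fit_ogden(cv, fit_config(rng_seed = 2, n_multistarts = 8))
  expect_true(is_stable(fr$params))
  # prediction collapses toward zero near the reference state
  expect_lt(abs(uniaxial_nominal_stress(fr$params, 1.01)), 1e-3)
})

test_that("cohort summaries use the population SD convention", {
  # closed forms for n = 1 and n = 2
  p1 <- ogden_params(c(0.01, 0.02), c(1, 10))
  s1 <- cohort_summary(list(p1))
  expect_equal(unname(s1$mean), c(0.01, 0.02, 1, 10))
  expect_true(all(s1$sd == 0))
  p2 <- ogden_params(c(0.03, 0.04), c(3, 20))
  s2 <- cohort_summary(list(p1, p2))
  expect_equal(unname(s2$mean["mu1"]), 0.02)
  expect_equal(unname(s2$sd["mu1"]), abs(0.01 - 0.03) / 2)
  expect_equal(unname(s2$sd["alpha1"]), 1)
  # mixed term counts are rejected
  expect_error(cohort_summary(list(p1, ogden_params(0.01, 5))), "same number")
})

test_that("the packaged porcine cohort reproduces its published statistics", {
  df <- porcine_lam_parameters()
  expect_equal(nrow(df), 20)
  s <- cohort_summary(porcine_lam_ogden_list())
  expect_equal(round(unname(s$mean["alpha1"]), 4), 0.1803)
  expect_equal(round(unname(s$sd["alpha1"]), 4), 0.1299)
  expect_equal(round(unname(s$mean["mu2"]), 4), 0.0216)
  expect_equal(round(unname(s$sd["mu2"]), 4), 0.0173)
})
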