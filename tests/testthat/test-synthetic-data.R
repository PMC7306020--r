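noiseless_spec <- function(...) {
  cohort_spec(force_noise_rel = 0, ...)
}

test_that("generated records follow the constant-velocity protocol exactly", {
  spec <- noiseless_spec(rupture_stretch_range = c(1.50001, 1.50009))
  g <- specimen_geometry(6, 4, 10)
  truth <- ogden_params(c(0.0029, 0.0584), c(0.2267, 14.055))
  rec <- generate_specimen(truth, g, spec, seed = 12)
  v <- 6 / 60
  expect_equal(diff(rec$elongation_mm), v * diff(rec$time_s), tolerance = 1e-12)
  # rupture at lambda = 1.5, gauge 10 mm, 6 mm/min: 50 s ramp at 10 Hz,
  # i.e. 500 samples after the zero-time reference sample, then the drop
  n_ramp <- length(rec$time_s) - 3L  # three post-rupture samples
  expect_equal(rec$time_s[n_ramp], 50, tolerance = 1e-6)
  expect_identical(n_ramp, 501L)
  # the post-rupture force collapse is detectable
  expect_lt(rec$force_n[length(rec$force_n)], 0.1 * max(rec$force_n))
})

test_that("zero-noise generation and reduction round-trip the Ogden law", {
  spec <- noiseless_spec()
  truth <- ogden_params(c(0.0059, 0.0352), c(0.2094, 20.608))
  g <- specimen_geometry(5.8, 4.1, 10)
  rec <- generate_specimen(truth, g, spec, seed = 4)
  cv <- truncate_at_rupture(to_stress_strain(rec))
  pred <- uniaxial_nominal_stress(truth, cv$stretch)
  rel <- abs(cv$nominal_stress_mpa - pred) / pmax(abs(pred), 1e-12)
  expect_lt(max(rel[-1]), 1e-9)  # first sample is exactly 0/0-free via pmax
})

test_that("records are deterministic in the seed", {
  spec <- cohort_spec()
  truth <- porcine_lam_ogden_list()[[9]]
  g <- specimen_geometry(6, 4, 10)
  a <- generate_specimen(truth, g, spec, seed = 77)
  b <- generate_specimen(truth, g, spec, seed = 77)
  expect_identical(a$force_n, b$force_n)
  c <- generate_specimen(truth, g, spec, seed = 78)
  expect_false(identical(a$force_n, c$force_n))
})

test_that("cohort generation is reproducible and manifest-complete", {
  spec <- cohort_spec(n_specimens = 3, rng_seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(length(a$records), 3L)
  expect_identical(names(a$manifest), vapply(a$records, function(r)
    r$specimen_id, character(1)))
  expect_identical(a$records[[2]]$force_n, b$records[[2]]$force_n)
  # fixed-table mode maps row i of the truth table to specimen i
  expect_identical(a$manifest[[1]]$mu, porcine_lam_ogden_list()[[1]]$mu)
  # truth table shorter than the cohort is a validation error
  expect_error(cohort_spec(n_specimens = 30), ">= 30")
})

test_that("preconditioning cycles precede the final ramp and reduce away", {
  spec <- noiseless_spec(precondition = TRUE)
  truth <- ogden_params(0.005, 10)
  g <- specimen_geometry(6, 4, 10)
  rec <- generate_specimen(truth, g, spec, seed = 9)
  expect_true(any(diff(rec$elongation_mm) < 0))  # cycles really go down
  cv <- truncate_at_rupture(to_stress_strain(rec))
  pred <- uniaxial_nominal_stress(truth, cv$stretch)
  rel <- abs(cv$nominal_stress_mpa - pred) / pmax(abs(pred), 1e-12)
  expect_lt(max(rel[-1]), 1e-9)
})

test_that("fitted stress error grows with the force-noise level", {
  noise_rmse <- function(noise) {
    vals <- vapply(1:10, function(s) {
      spec <- cohort_spec(force_noise_rel = noise, rng_seed = 100 + s,
                          n_specimens = 1)
      co <- generate_cohort(spec)
      cv <- truncate_at_rupture(to_stress_strain(co$records[[1]]))
      fit_ogden(cv, fit_config(rng_seed = s, n_multistarts = 6))$rmse_mpa
    }, numeric(1))
    mean(vals)
  }
  r0 <- noise_rmse(0)
  r1 <- noise_rmse(0.005)
  r2 <- noise_rmse(0.02)
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})

test_that("cohort directories round-trip records and ground-truth manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_specimens = 2, rng_seed = 3))
  write_cohort_dir(co, dir)
  files <- list.files(dir, pattern = "specimen_.*\\.csv")
  expect_identical(length(files), 2L)
  back <- read_specimen_csv(file.path(dir, "specimen_01.csv"))
  expect_equal(back$force_n, co$records[[1]]$force_n, tolerance = 1e-15)
  man <- read_cohort_manifest(file.path(dir, "manifest.json"))
  expect_identical(man$specimen_01$mu, co$manifest$specimen_01$mu)
})
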