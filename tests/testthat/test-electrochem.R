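test_that("peak current follows the square-root diffusion law", {
  expect_equal(randles_sevcik_current(1, 1, 1e-6, 1e-5, 0.1),
               2.69e5 * 1e-6 * sqrt(1e-6), tolerance = 1e-12)
  i1 <- randles_sevcik_current(1, 0.07, 2e-6, 1e-5, 0.1)
  expect_equal(randles_sevcik_current(1, 0.07, 4e-6, 1e-5, 0.1) / i1, 2)
  expect_equal(randles_sevcik_current(2, 0.07, 2e-6, 1e-5, 0.1) / i1,
               2^1.5)
  expect_error(randles_sevcik_current(1, -1, 1e-6, 1e-5, 0.1), "> 0")
})

test_that("dilution series follows the closed-form schedule", {
  expect_equal(dilution_series(2.0, 0.5, 6, 1),
               c(1, 0.8, 2/3, 4/7, 0.5, 4/9, 0.4), tolerance = 1e-12)
  expect_equal(dilution_series(2.0, 0, 4, 0.3), rep(0.3, 5))
  expect_equal(dilution_series(2.0, 0.5, 0, 0.3), 0.3)
  s <- dilution_series(1.7, 0.3, 8, 0.02)
  expect_true(all(diff(s) < 0))            # strictly decreasing
})

test_that("calibration fitting accepts exact lines and reports r-squared", {
  C <- dilution_series(2.0, 0.5, 6, 0.01)
  fit <- fit_calibration(C, 2 * C + 0.1)
  expect_true(is_accepted(fit))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_calibration(rep(0.5, 4), 1:4), "degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3")
})

test_that("sub-threshold calibrations are rejected carrying their r-squared", {
  # perturb an exact line along the OLS-orthogonal direction until the
  # closed-form r^2 hits the target
  C <- dilution_series(2.0, 0.5, 6, 0.01)
  y0 <- 3 * C + 0.05
  set.seed(11)
  e <- resid(lm(rnorm(length(C)) ~ C))
  target <- 0.95
  # r2 = 1 - k^2 ss_e / (ss_f + k^2 ss_e) for y = y0 + k e
  ss_f <- sum((y0 - mean(y0))^2); ss_e <- sum(e^2)
  k <- sqrt(ss_f * (1 - target) / (target * ss_e))
  fit <- fit_calibration(C, y0 + k * e)
  expect_false(is_accepted(fit))
  expect_s3_class(fit, "calibration_rejection")
  expect_equal(fit$r_squared, 0.95, tolerance = 1e-9)
  expect_error(solubility_from_cv(fit, 1), "rejected")
})

test_that("r-squared is invariant under affine rescaling of the current", {
  C <- dilution_series(2.0, 0.5, 6, 0.02)
  set.seed(4)
  i <- 5 * C + 0.2 + rnorm(length(C), 0, 0.005)
  f1 <- fit_calibration(C, i)
  f2 <- fit_calibration(C, 1e3 * i + 42)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("solubility determination inverts the calibration line", {
  C <- dilution_series(2.0, 0.5, 6, 0.01)
  fit <- fit_calibration(C, 2 * C)
  expect_equal(suppressWarnings(solubility_from_cv(fit, 1, 10)), 5)
  expect_error(suppressWarnings(solubility_from_cv(fit, 0, 1)),
               "not positive")
  expect_warning(solubility_from_cv(fit, 1, 10), "outside")
})

test_that("noise-free end-to-end round trip recovers the known solubility", {
  fx <- make_calibration_fixture(true_slope = 40, intercept = 0.003,
                                 noise_sd = 0,
                                 schedule = dilution_series(2, 0.5, 6, 0.01),
                                 seed = 2, true_solubility = 0.05,
                                 dilution_factor = 10)
  fit <- fit_calibration(fx$points$concentration, fx$points$current)
  expect_true(is_accepted(fit))
  S <- solubility_from_cv(fit, fx$saturated_current, 10)
  expect_equal(S, 0.05, tolerance = 1e-9)
})

test_that("noisy fixtures near the threshold are mostly rejected", {
  # noise tuned so the expected r^2 sits around 0.95, below the filter
  C <- dilution_series(2.0, 0.5, 6, 0.01)
  sig <- sd(40 * C)
  s_noise <- sig * sqrt((1 - 0.95) / 0.95)
  rejected <- 0
  for (seed in 1:40) {
    fx <- make_calibration_fixture(40, 0, noise_sd = s_noise,
                                   schedule = C, seed = seed)
    f <- fit_calibration(fx$points$concentration, fx$points$current)
    rejected <- rejected + !is_accepted(f)
  }
  expect_gt(rejected, 20)
})
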