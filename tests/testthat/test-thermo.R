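test_that("lattice energy arithmetic normalizes per molecule", {
  expect_equal(lattice_energy(-10, rep(-2.4, 4), Z = 4), -0.1)
  expect_equal(lattice_energy(-7.2, rep(-2.4, 3)), 0)       # no cohesion
  expect_equal(lattice_energy(-5, -3, Z = 1), -2)
  expect_error(lattice_energy(-5, c(-1, -2), Z = 3), "Z")
})

test_that("sublimation enthalpy carries the -2RT offset", {
  expect_equal(dH_sub_from_Ulatt(-100, 298.15), 95.042, tolerance = 1e-5)
  expect_equal(dH_sub_from_Ulatt(-100, 0), 100)            # T -> 0 limit
  expect_equal(dH_sub_from_Ulatt(0, 298.15),
               -2 * 8.31446e-3 * 298.15)
})

test_that("sublimation entropy composes linearly from its parts", {
  expect_equal(dS_sub_compose(0, 0, 0), 0)
  expect_equal(dS_sub_compose(100, 30, 20), 50)
  expect_equal(dS_sub_compose(-100, -30, -20), -50)        # sign flip
})

test_that("cycle logS conversion and its inverse are exact partners", {
  # dG_sol = ln(10) R T with V_m = 1 gives logS = -1
  kT <- log(10) * 8.31446e-3 * 298.15
  expect_equal(logS_from_cycle(kT, 0, 0, V_m = 1), -1, tolerance = 1e-12)
  expect_equal(logS_from_cycle(0, 0, 0, V_m = 1), 0)

  set.seed(7)
  for (i in 1:25) {
    dG <- rnorm(1, -40, 15); dH <- rnorm(1, 100, 25)
    dS <- rnorm(1, 180, 50); Vm <- runif(1, 0.05, 0.5)
    ls <- logS_from_cycle(dG, dH, dS, Vm)
    dG_sol <- dG_sol_from_logS(ls, Vm)
    # recompose the cycle from the recovered free energy
    expect_equal(-dG_sol / (log(10) * 8.31446e-3 * 298.15) - log10(Vm),
                 ls, tolerance = 1e-12)
  }
  expect_error(logS_from_cycle(0, 0, 0, V_m = -1), "V_m")
  expect_error(logS_from_cycle(0, 0, 0, V_m = 1, T_K = 0), "temperature")
})

test_that("parametrized model evaluates the printed functional form", {
  co <- published_thermo_coefficients()
  # all-zero inputs with V_m = 1 leave only the offset
  expect_equal(thermo_model_predict(co, 0, 0, 0, 1), -0.540)
  expect_equal(
    thermo_model_predict(co, -10, 20, 0, 1),
    -0.38075 * 10 - 0.107058 * 20 - 0.540, tolerance = 1e-12)
  # beta = 0 reduces to an affine model in dG_solv and log10 V_m
  c0 <- thermo_coefficients(0.4, 0, 0.1, 0.2)
  expect_equal(thermo_model_predict(c0, -5, 123, 456, 10),
               0.4 * -5 - 0.1 * 1 - 0.2)
  expect_error(thermo_model_predict(co, 0, 0, 0, 1, unit_system = "kcal"),
               "unit mismatch")
})

test_that("quasi-Newton fit recovers generating coefficients exactly without noise", {
  co <- published_thermo_coefficients()
  d <- make_thermo_table(n = 44, seed = 42, coef = co)
  fit <- fit_thermo_model(d)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$alpha, co$alpha, tolerance = 1e-6)
  expect_equal(fit$coefficients$beta, co$beta, tolerance = 1e-6)
  expect_equal(fit$coefficients$gamma, co$gamma, tolerance = 1e-6)
  expect_equal(fit$coefficients$delta, co$delta, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("quasi-Newton fit equals closed-form least squares", {
  for (seed in 1:5) {
    d <- make_thermo_table(n = 30, seed = seed, coef = NULL, noise_sd = 0.5)
    fit <- fit_thermo_model(d)
    A <- cbind(d$dG_solv, -(d$dH_sub - d$dS_sub * 298.15 / 1000),
               -log10(d$V_m))
    ls <- stats::lm(d$logS ~ A)
    expect_lt(abs(fit$coefficients$alpha - coef(ls)[2]), 1e-8)
    expect_lt(abs(fit$coefficients$beta - coef(ls)[3]), 1e-8)
    expect_lt(abs(fit$coefficients$gamma - coef(ls)[4]), 1e-8)
    expect_lt(abs(fit$coefficients$delta + coef(ls)[1]), 1e-8)
  }
})

test_that("fit is invariant to row permutation and initialization", {
  d <- make_thermo_table(n = 40, seed = 3, coef = NULL, noise_sd = 0.3)
  f1 <- fit_thermo_model(d)
  f2 <- fit_thermo_model(d[sample(nrow(d)), ])
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-9)
  f3 <- fit_thermo_model(d, init = thermo_coefficients(5, -3, 2, 10))
  expect_equal(unlist(f1$coefficients[1:4]), unlist(f3$coefficients[1:4]),
               tolerance = 1e-6)
})

test_that("degenerate constant target collapses to the intercept", {
  d <- make_thermo_table(n = 20, seed = 5)
  d$logS <- 2.5
  fit <- fit_thermo_model(d)
  expect_equal(fit$coefficients$delta, -2.5, tolerance = 1e-6)
  expect_lt(abs(fit$coefficients$alpha), 1e-6)
  expect_equal(fit$rmse, 0, tolerance = 1e-7)
})

test_that("noisy coefficient recovery is unbiased at the study scale", {
  co <- published_thermo_coefficients()
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 4)
  for (r in seq_len(n_rep)) {
    d <- make_thermo_table(n = 44, seed = 1000 + r, coef = co,
                           noise_sd = 0.3)
    f <- fit_thermo_model(d)
    est[r, ] <- c(f$coefficients$alpha, f$coefficients$beta,
                  f$coefficients$gamma, f$coefficients$delta)
  }
  truth <- c(co$alpha, co$beta, co$gamma, co$delta)
  ctr <- colMeans(est)
  hw <- 3.29 * apply(est, 2, sd) / sqrt(n_rep)   # 99.9% CI on the mean
  expect_true(all(abs(ctr - truth) < hw))
})
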