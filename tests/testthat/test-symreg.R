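# wrap a plain matrix as a leaf-only candidate_set for l0 tests
expand_leaves <- function(X, y) {
  structure(list(
    M = X, strs = colnames(X),
    complexity = rep(1L, ncol(X)),
    target = y, row_ids = as.character(seq_len(nrow(X))),
    unit_system = "kJ",
    dropped = data.frame(candidate = character(), reason = character())
  ), class = "candidate_set")
}

test_that("MI screening ranks an exact copy of the target first", {
  set.seed(1)
  X <- cbind(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- X[, "b"]
  fm <- feature_matrix(X, target = y)
  expect_equal(mi_screen(fm, 1)[1], "b")
  expect_setequal(mi_screen(fm, 3), c("a", "b", "c"))
  expect_error(mi_screen(fm, 0), "config")
  expect_error(mi_screen(fm, 9), "config")
})

test_that("MI screening prefers a noisy transform over pure noise", {
  wins <- 0
  for (s in 1:40) {
    set.seed(s)
    y <- rnorm(200)
    X <- cbind(transform = y^3 + rnorm(200, 0, 0.4),
               noise = rnorm(200))
    fm <- feature_matrix(X, target = y)
    wins <- wins + (mi_screen(fm, 1)[1] == "transform")
  }
  expect_gte(wins, 38)     # >= 95% of replicates
})

test_that("depth-1 expansion enumerates exactly the expected set", {
  set.seed(2)
  X <- cbind(a = runif(20, 1, 2), b = runif(20, 1, 2))
  fm <- feature_matrix(X, target = rnorm(20))
  cs <- expand_features(c("a", "b"), fm, operators = c("+", "*", "^2"),
                        depth = 1)
  expect_setequal(cs$strs,
                  c("a", "b", "(+ a b)", "(* a b)", "(^2 a)", "(^2 b)"))
})

test_that("expansion removes canonical duplicates and guards division", {
  set.seed(3)
  a <- runif(20, 1, 2)
  X <- cbind(a = a, dup = a, z = c(0, runif(19, 1, 2)))
  fm <- feature_matrix(X, target = rnorm(20))
  cs <- expand_features(colnames(X), fm, depth = 1)
  expect_false(anyDuplicated(cs$strs) > 0)
  # division by the zero-containing column must be dropped and logged
  expect_false("(/ a z)" %in% cs$strs)
  expect_true("(/ a z)" %in% cs$dropped$candidate)
  expect_true(all(is.finite(cs$M)))
  # constant combinations (a - dup) are dropped as well
  expect_true(any(cs$dropped$reason == "constant"))
  expect_error(expand_features(colnames(X), fm, depth = 2, cap = 10),
               "cap")
})

test_that("SIS keeps an exact target copy and is the identity at full size", {
  set.seed(4)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, sprintf("c%02d", 1:10)))
  y <- X[, 3]
  cs <- expand_leaves(X, y)
  kept <- sis_filter(cs, 4)
  expect_true("c03" %in% kept$strs)
  full <- sis_filter(cs, 10)
  expect_setequal(full$strs, colnames(X))
  expect_error(sis_filter(cs, 11), "exceeds")
})

test_that("SIS retains a planted linear predictor among random candidates", {
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    X <- matrix(rnorm(100 * 21), 100, 21,
                dimnames = list(NULL, c(sprintf("n%02d", 1:20), "planted")))
    y <- 2 * X[, "planted"] + rnorm(100, 0, 0.5)
    cs <- expand_leaves(X, y)
    hits <- hits + ("planted" %in% sis_filter(cs, 5)$strs)
  }
  expect_equal(hits, 30)   # >= 99% of replicates
})

test_that("l0 regression recovers an exact sparse generator", {
  set.seed(5)
  X <- matrix(rnorm(400), 40, 10,
              dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- 2 * X[, 3] - X[, 7]
  cs <- expand_leaves(X, y)
  mod <- l0_regress(cs, max_support = 3)
  expect_setequal(model_support(mod), c("x03", "x07"))
  co <- vapply(mod$terms, `[[`, numeric(1), "coefficient")
  names(co) <- model_support(mod)
  expect_equal(unname(co["x03"]), 2, tolerance = 1e-9)
  expect_equal(unname(co["x07"]), -1, tolerance = 1e-9)
  expect_equal(mod$r_squared, 1, tolerance = 1e-12)
})

test_that("infinite penalty collapses to the intercept-only mean model", {
  set.seed(6)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, sprintf("x%02d", 1:10)))
  y <- rnorm(20, 5)
  mod <- l0_regress(expand_leaves(X, y), max_support = 3, penalty = 1e12)
  expect_length(mod$terms, 0)
  expect_equal(mod$intercept, mean(y), tolerance = 1e-12)
})

test_that("compiled subset search equals a brute-force enumerator", {
  # independent oracle: enumerate all supports of size <= 3 from 8
  # candidates with lm(), pick minimal penalized MSE
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(35 * 8), 35, 8,
                dimnames = list(NULL, sprintf("x%d", 1:8)))
    y <- X[, 2] - 0.5 * X[, 5] + rnorm(35, 0, 0.4)
    pen <- 0.01
    best <- list(obj = Inf)
    for (s in 0:3) {
      for (sup in if (s == 0) list(integer(0)) else
           asplit(utils::combn(8, s), 2)) {
        d <- as.data.frame(X[, sup, drop = FALSE])
        fit <- if (s == 0) stats::lm(y ~ 1) else stats::lm(y ~ ., data = d)
        obj <- mean(resid(fit)^2) + pen * s
        if (obj < best$obj - 1e-12) {
          best <- list(obj = obj, support = sort(colnames(X)[sup]),
                       coef = coef(fit))
        }
      }
    }
    mod <- l0_regress(expand_leaves(X, y), max_support = 3, penalty = pen)
    expect_equal(model_support(mod), best$support)
    co <- vapply(mod$terms, `[[`, numeric(1), "coefficient")
    names(co) <- vapply(mod$terms,
                        function(t) format_expression(t$expression),
                        character(1))
    for (nm in best$support) {
      expect_equal(unname(co[nm]), unname(best$coef[nm]),
                   tolerance = 1e-9)
    }
    expect_equal(mod$intercept, unname(best$coef[1]), tolerance = 1e-9)
  }
})

test_that("l0 objective is monotone non-increasing in max_support", {
  set.seed(8)
  X <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, sprintf("x%d", 1:8)))
  y <- X[, 1] + 0.5 * X[, 2] - 0.3 * X[, 4] + rnorm(40, 0, 0.3)
  cs <- expand_leaves(X, y)
  mses <- vapply(0:4, function(k)
    l0_regress(cs, max_support = k)$rmse^2, numeric(1))
  expect_true(all(diff(mses) <= 1e-12))
})

test_that("published model structure evaluates as printed", {
  pm <- published_solubility_model()
  zero <- matrix(0, 3, 10,
                 dimnames = list(NULL, c("dG_solv", "dH_sub",
                                         published_descriptor_names())))
  expect_equal(evaluate(pm, zero), rep(1.55106, 3))
  # doubling dG_solv doubles exactly the first term
  set.seed(9)
  X <- matrix(runif(30, 0.5, 2), 3, 10,
              dimnames = dimnames(zero))
  X2 <- X; X2[, "dG_solv"] <- 2 * X2[, "dG_solv"]
  t1 <- function(M) 0.3014 * M[, "dG_solv"] *
    (M[, "Xp4dv"] - M[, "Xp6dv"]) * M[, "ETA_alpha"]
  expect_equal(evaluate(pm, X2) - evaluate(pm, X), t1(X2) - t1(X),
               tolerance = 1e-12)
  # fraction reading divides by the trailing factor
  pf <- published_solubility_model("fraction")
  expect_equal(
    evaluate(pf, X)[1],
    unname(1.55106 +
      0.3014 * X[1, "dG_solv"] * (X[1, "Xp4dv"] - X[1, "Xp6dv"]) /
        X[1, "ETA_alpha"] -
      0.004736 * X[1, "Xp7dv"] * (X[1, "dH_sub"] - X[1, "ASA"]) /
        X[1, "JGI2"] -
      0.04027 * X[1, "MWC07"] * X[1, "Xp6dv"] /
        (X[1, "ETA_alpha"] - X[1, "ATSC3s"])),
    tolerance = 1e-12)
  expect_error(evaluate(pm, zero[, 1:5]), "schema")
})

test_that("structure refit reproduces generating coefficients and shifts", {
  set.seed(10)
  X <- matrix(runif(44 * 10, 0.5, 2), 44, 10,
              dimnames = list(NULL, c("dG_solv", "dH_sub",
                                      published_descriptor_names())))
  pm <- published_solubility_model()
  y <- evaluate(pm, X)
  fm <- feature_matrix(X, target = y)
  refit <- refit_structure(pm, fm)
  for (i in seq_along(pm$terms)) {
    expect_equal(refit$terms[[i]]$coefficient, pm$terms[[i]]$coefficient,
                 tolerance = 1e-9)
  }
  expect_equal(refit$intercept, pm$intercept, tolerance = 1e-9)

  fm2 <- feature_matrix(X, target = y + 1)
  refit2 <- refit_structure(pm, fm2)
  expect_equal(refit2$intercept, refit$intercept + 1, tolerance = 1e-9)
  for (i in seq_along(pm$terms)) {
    expect_equal(refit2$terms[[i]]$coefficient,
                 refit$terms[[i]]$coefficient, tolerance = 1e-9)
  }

  # refit is least-squares optimal on the refit data
  set.seed(11)
  y3 <- y + rnorm(44, 0, 0.5)
  fm3 <- feature_matrix(X, target = y3)
  refit3 <- refit_structure(pm, fm3)
  expect_lte(mean((y3 - evaluate(refit3, fm3))^2),
             mean((y3 - evaluate(pm, fm3))^2) + 1e-12)

  expect_error(refit_structure(pm, fm_single <- feature_matrix(
    X[1, , drop = FALSE], target = y[1])), "rank")
})

test_that("model JSON serialization round-trips", {
  pm <- published_solubility_model()
  path <- tempfile(fileext = ".json")
  write_symbolic_model(pm, path)
  back <- read_symbolic_model(path)
  expect_equal(model_support(back), model_support(pm))
  expect_equal(back$intercept, pm$intercept)
  expect_equal(back$unit_system, pm$unit_system)
  expect_equal(vapply(back$terms, `[[`, numeric(1), "coefficient"),
               vapply(pm$terms, `[[`, numeric(1), "coefficient"))
})

test_that("discovery is deterministic and invariant to row/column order", {
  gen <- generate_synthetic(synthetic_spec(seed = 21))
  m1 <- discover(gen$fm, seed = 7)
  m2 <- discover(gen$fm, seed = 7)
  expect_identical(model_support(m1), model_support(m2))
  expect_equal(m1$r_squared, m2$r_squared, tolerance = 1e-12)

  perm <- sample(nrow(gen$fm$X))
  fm_p <- feature_matrix(gen$fm$X[perm, rev(seq_len(ncol(gen$fm$X)))],
                         target = gen$fm$target[perm])
  m3 <- discover(fm_p, seed = 7)
  expect_identical(model_support(m3), model_support(m1))
})

test_that("noise-free planted law is recovered with perfect fit", {
  spec <- synthetic_spec(seed = 5, noise_sd = 0)
  gen <- generate_synthetic(spec)
  m <- discover(gen$fm, seed = 5)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_identical(model_support(m), model_support(gen$truth$law))
})
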