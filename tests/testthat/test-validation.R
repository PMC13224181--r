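test_that("metrics match their definitions", {
  y <- c(1, 2, 3, 6)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 4)), 0)
  # hand-computed 4-point case
  yhat <- c(1.5, 2, 2.5, 5)
  ss_res <- sum((y - yhat)^2); ss_tot <- sum((y - 3)^2)
  expect_equal(r2(y, yhat), 1 - ss_res / ss_tot)
  expect_error(r2(rep(2, 4), 1:4), "constant")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 0.7), 0.7)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  # independent two-pass computation
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50), tolerance = 1e-12)
})

test_that("fold assignments partition the rows", {
  f <- make_folds(44, 5, seed = 3)
  expect_length(f, 44)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f) %in% c(8, 9)))
  expect_identical(f, make_folds(44, 5, seed = 3))
  expect_false(identical(f, make_folds(44, 5, seed = 4)))
  expect_error(make_folds(8, 5), "2k")
})

test_that("fixed-structure CV is perfect on noise-free model data", {
  set.seed(2)
  X <- matrix(runif(44 * 10, 0.5, 2), 44, 10,
              dimnames = list(NULL, c("dG_solv", "dH_sub",
                                      published_descriptor_names())))
  pm <- published_solubility_model()
  fm <- feature_matrix(X, target = evaluate(pm, X))
  rep5 <- fixed_structure_cv(pm, fm, k = 5, seed = 1)
  expect_equal(rep5$per_fold$r2, rep(1, 5), tolerance = 1e-9)
  expect_equal(rep5$mean_RMSE, 0, tolerance = 1e-9)
  # determinism
  rep5b <- fixed_structure_cv(pm, fm, k = 5, seed = 1)
  expect_equal(rep5$per_fold, rep5b$per_fold)
  expect_identical(rep5$fold_assignments, rep5b$fold_assignments)
  # aggregates recomputable from the per-fold table
  expect_equal(rep5$mean_R2, mean(rep5$per_fold$r2), tolerance = 1e-12)
})

test_that("shuffled targets give no held-out skill", {
  set.seed(4)
  X <- matrix(runif(44 * 10, 0.5, 2), 44, 10,
              dimnames = list(NULL, c("dG_solv", "dH_sub",
                                      published_descriptor_names())))
  pm <- published_solubility_model()
  y <- evaluate(pm, X)
  r2s <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    fm <- feature_matrix(X, target = sample(y))
    fixed_structure_cv(pm, fm, k = 5, seed = s)$mean_R2
  }, numeric(1))
  expect_lte(mean(r2s), 0.1)
})

test_that("full-rerun CV approaches the generator noise ceiling", {
  spec <- synthetic_spec(seed = 31)
  gen <- generate_synthetic(spec)
  cfg <- discover_config()
  rep_cv <- full_rerun_cv(cfg, gen$fm, k = 5, seeds = 1:2)
  expect_true(abs(rep_cv$aggregate_R2 - gen$truth$ceiling_r2) <= 0.15)
  expect_length(rep_cv$models, 10)
  # single-seed list reduces to plain CV of the discovery
  rep1 <- full_rerun_cv(cfg, gen$fm, k = 5, seeds = 7)
  expect_equal(nrow(rep1$per_fold), 5)
  expect_equal(rep1$aggregate_R2,
               r2(gen$fm$target, rep1$per_sample_mean_predictions),
               tolerance = 1e-12)
})

test_that("training-fold refits are unaffected by held-out outliers", {
  # leakage guard: corrupting a single held-out row must not change the
  # training-fold refit of that fold
  set.seed(6)
  X <- matrix(runif(44 * 10, 0.5, 2), 44, 10,
              dimnames = list(NULL, c("dG_solv", "dH_sub",
                                      published_descriptor_names())))
  pm <- published_solubility_model()
  y <- evaluate(pm, X) + rnorm(44, 0, 0.2)
  folds <- make_folds(44, 5, seed = 2)
  out_row <- which(folds == 1)[1]
  y_b <- y; y_b[out_row] <- y_b[out_row] + 1e4
  train <- folds != 1
  refit_a <- refit_structure(pm, feature_matrix(X[train, ],
                                                target = y[train]))
  refit_b <- refit_structure(pm, feature_matrix(X[train, ],
                                                target = y_b[train]))
  expect_equal(vapply(refit_a$terms, `[[`, numeric(1), "coefficient"),
               vapply(refit_b$terms, `[[`, numeric(1), "coefficient"),
               tolerance = 1e-12)
})

test_that("ensemble baseline is reproducible and overfits less data than it memorizes", {
  gen <- generate_synthetic(synthetic_spec(seed = 8))
  b1 <- baseline_ensemble_cv(gen$fm, k = 5, seed = 2, ntree = 150)
  b2 <- baseline_ensemble_cv(gen$fm, k = 5, seed = 2, ntree = 150)
  expect_equal(b1$train_r2, b2$train_r2, tolerance = 1e-12)
  expect_equal(b1$cv_r2, b2$cv_r2, tolerance = 1e-12)
  expect_gt(b1$train_r2, b1$cv_r2)      # resubstitution optimism
  expect_equal(b1$hyperparams$ntree, 150)
})

test_that("ensemble train-cv gap shrinks with more data", {
  gap_at <- function(n, seed) {
    spec <- synthetic_spec(n_compounds = n, seed = seed)
    gen <- generate_synthetic(spec)
    b <- baseline_ensemble_cv(gen$fm, k = 5, seed = seed, ntree = 200)
    b$train_r2 - b$cv_r2
  }
  gaps_small <- vapply(1:3, function(s) gap_at(44, s), numeric(1))
  gaps_large <- vapply(1:3, function(s) gap_at(400, s), numeric(1))
  expect_lt(mean(gaps_large), mean(gaps_small))
})

test_that("feature recurrence counts references across models", {
  m1 <- symbolic_model(list(list(coefficient = 1,
                                 expression = ex_op("*", "a", "b"))), 0)
  m2 <- symbolic_model(list(list(coefficient = 1,
                                 expression = ex_op("-", "a", "c"))), 0)
  m3 <- symbolic_model(list(list(coefficient = 2,
                                 expression = ex_var("a"))), 0)
  tab <- feature_recurrence(list(m1, m2, m3))
  expect_equal(tab$recurrence[tab$descriptor == "a"], 1)
  expect_equal(tab$recurrence[tab$descriptor == "b"], 1 / 3)
  expect_false("d" %in% tab$descriptor)
  # identical models: every referenced descriptor at 1.0
  tab2 <- feature_recurrence(list(m1, m1))
  expect_true(all(tab2$recurrence == 1))
})
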