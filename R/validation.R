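## Validation protocols for small-data solubility models.
##
## Two cross-validation stress tests: a fixed-structure protocol that
## freezes a discovered symbolic form and re-estimates only its
## coefficients per training fold, and a full-rerun protocol that
## repeats the entire discovery workflow inside every fold across
## several seeds (aggregating per-sample mean predictions).  A
## bagged-tree ensemble trained under the same fold scheme provides the
## overfitting benchmark.

#' Coefficient of determination
#'
#' 1 - SS_res/SS_tot.  May be negative on held-out data; undefined for
#' a constant target.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions.
#' @return R^2.
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("undefined metric: constant target", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#' @param y observed values.
#' @param yhat predictions (equal length).
#' @return RMSE in the units of `y` (logS units throughout this package).
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sqrt(mean((y - yhat)^2))
}

#' Seeded uniform random fold assignment
#'
#' Uniform random partition into `k` folds of near-equal size, no
#' stratification; the seed is always recorded by the callers.
#'
#' @param n number of rows.
#' @param k number of folds (2 <= k, n >= 2k).
#' @param seed integer seed.
#' @return Integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("need k >= 2 folds", call. = FALSE)
  if (n < 2L * k) stop("need n >= 2k rows", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

.cv_report <- function(protocol, folds, per_fold, seeds,
                       per_sample_mean = NULL, extra = list()) {
  ok <- !is.na(per_fold$r2)
  structure(c(list(
    protocol = protocol, fold_assignments = folds, per_fold = per_fold,
    mean_R2 = mean(per_fold$r2[ok]), sd_R2 = stats::sd(per_fold$r2[ok]),
    mean_RMSE = mean(per_fold$rmse[ok]), sd_RMSE = stats::sd(per_fold$rmse[ok]),
    per_sample_mean_predictions = per_sample_mean, seeds = seeds
  ), extra), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report [%s]: mean R^2 = %.3f (sd %.3f), mean RMSE = %.3f (sd %.3f)\n",
              x$protocol, x$mean_R2, x$sd_R2, x$mean_RMSE, x$sd_RMSE))
  if (!is.null(x$aggregate_R2)) {
    cat(sprintf("  aggregate (per-sample mean predictions): R^2 = %.3f, RMSE = %.3f\n",
                x$aggregate_R2, x$aggregate_RMSE))
  }
  cat(sprintf("  folds: %s; seeds: %s\n",
              paste(table(x$fold_assignments), collapse = "/"),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Fixed-structure k-fold cross-validation
#'
#' Holds the symbolic structure of `model` fixed; within each fold only
#' the numerical coefficients are re-estimated on the training rows
#' ([refit_structure()]) and the refit model is evaluated on the
#' held-out rows.  A stress test of structural stability rather than an
#' unbiased generalization estimate when the structure was selected on
#' the full data.
#'
#' @param model a `symbolic_model`.
#' @param fm a `feature_matrix` with target.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return A `cv_report` (protocol `"fixed_structure_kfold"`) with
#'   per-fold and aggregate R^2/RMSE, the fold assignment and the seed.
#'   Folds whose refit fails are marked failed and excluded with a
#'   warning.
#' @export
fixed_structure_cv <- function(model, fm, k = 5L, seed = 1L) {
  stopifnot(inherits(model, "symbolic_model"),
            inherits(fm, "feature_matrix"), !is.null(fm$target))
  folds <- make_folds(nrow(fm$X), k = k, seed = seed)
  per_fold <- data.frame(fold = seq_len(k), r2 = NA_real_, rmse = NA_real_)
  preds <- rep(NA_real_, nrow(fm$X))
  for (f in seq_len(k)) {
    test <- folds == f
    refit <- tryCatch(refit_structure(model, fm_rows(fm, !test)),
                      error = function(e) e)
    if (inherits(refit, "error")) {
      warning("fold ", f, " refit failed (", conditionMessage(refit),
              "); excluded", call. = FALSE)
      next
    }
    p <- evaluate(refit, fm_rows(fm, test))
    preds[test] <- p
    per_fold$r2[f] <- r2(fm$target[test], p)
    per_fold$rmse[f] <- rmse(fm$target[test], p)
  }
  .cv_report("fixed_structure_kfold", folds, per_fold, seeds = seed,
             per_sample_mean = preds)
}

#' Full-rerun repeated cross-validation
#'
#' Reruns the entire discovery workflow (screening, expansion,
#' selection) on the training rows of every fold, for each seed in
#' `seeds`; each seed uses its own fold assignment, so every sample
#' collects one held-out prediction per seed.  Aggregate metrics are
#' computed on the per-sample mean predictions (averaged over seeds
#' before the metric).  All discovered models are returned for
#' feature-recurrence analysis.
#'
#' @param config a [discover_config()].
#' @param fm a `feature_matrix` with target.
#' @param k folds per repetition.
#' @param seeds integer vector of repetition seeds.
#' @return A `cv_report` (protocol `"full_rerun_repeated"`) with
#'   additional elements `aggregate_R2`, `aggregate_RMSE` (on
#'   per-sample means) and `models` (all discovered structures).
#'   Failed (seed, fold) discoveries are recorded and excluded with a
#'   warning.
#' @export
full_rerun_cv <- function(config, fm, k = 5L, seeds = 1:5) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$target))
  n <- nrow(fm$X)
  pred_mat <- matrix(NA_real_, n, length(seeds))
  per_fold <- data.frame(seed = integer(), fold = integer(),
                         r2 = numeric(), rmse = numeric())
  models <- list()
  folds_by_seed <- list()
  for (si in seq_along(seeds)) {
    folds <- make_folds(n, k = k, seed = seeds[si])
    folds_by_seed[[si]] <- folds
    for (f in seq_len(k)) {
      test <- folds == f
      mod <- tryCatch(discover(fm_rows(fm, !test), config = config,
                               seed = seeds[si]),
                      error = function(e) e)
      if (inherits(mod, "error")) {
        warning("seed ", seeds[si], " fold ", f, " discovery failed (",
                conditionMessage(mod), "); excluded", call. = FALSE)
        per_fold <- rbind(per_fold,
                          data.frame(seed = seeds[si], fold = f,
                                     r2 = NA_real_, rmse = NA_real_))
        next
      }
      models[[length(models) + 1L]] <- mod
      p <- evaluate(mod, fm_rows(fm, test))
      pred_mat[test, si] <- p
      per_fold <- rbind(per_fold,
                        data.frame(seed = seeds[si], fold = f,
                                   r2 = r2(fm$target[test], p),
                                   rmse = rmse(fm$target[test], p)))
    }
  }
  mean_pred <- rowMeans(pred_mat, na.rm = TRUE)
  have <- is.finite(mean_pred)
  .cv_report("full_rerun_repeated",
             folds = do.call(cbind, folds_by_seed),
             per_fold = per_fold, seeds = seeds,
             per_sample_mean = mean_pred,
             extra = list(
               aggregate_R2 = r2(fm$target[have], mean_pred[have]),
               aggregate_RMSE = rmse(fm$target[have], mean_pred[have]),
               models = models))
}

#' Bagged-tree ensemble baseline under the same fold scheme
#'
#' Fits a random-forest regressor on the full matrix (training metric)
#' and under k-fold cross-validation with a seeded fold assignment (cv
#' metric).  Hyperparameters are library defaults with 500 trees and are
#' recorded verbatim in the report.
#'
#' @param fm a `feature_matrix` with target.
#' @param k folds.
#' @param seed fold-assignment and forest seed.
#' @param ntree,mtry,nodesize forest hyperparameters (defaults: 500
#'   trees, library defaults otherwise).
#' @return A list with `train_r2`, `cv_r2`, `hyperparams` and `report`
#'   (a `cv_report`, protocol `"baseline"`).
#' @export
baseline_ensemble_cv <- function(fm, k = 5L, seed = 1L, ntree = 500L,
                                 mtry = NULL, nodesize = 5L) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$target))
  X <- as.data.frame(fm$X)
  names(X) <- make.names(names(X))
  y <- fm$target
  if (is.null(mtry)) mtry <- max(floor(ncol(X) / 3), 1L)
  set.seed(seed)
  full <- randomForest::randomForest(X, y, ntree = ntree, mtry = mtry,
                                     nodesize = nodesize)
  train_pred <- stats::predict(full, X)   # resubstitution predictions
  folds <- make_folds(length(y), k = k, seed = seed)
  per_fold <- data.frame(fold = seq_len(k), r2 = NA_real_, rmse = NA_real_)
  preds <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    set.seed(seed + f)
    rf <- randomForest::randomForest(X[!test, , drop = FALSE], y[!test],
                                     ntree = ntree, mtry = mtry,
                                     nodesize = nodesize)
    p <- stats::predict(rf, X[test, , drop = FALSE])
    preds[test] <- p
    per_fold$r2[f] <- r2(y[test], p)
    per_fold$rmse[f] <- rmse(y[test], p)
  }
  report <- .cv_report("baseline", folds, per_fold, seeds = seed,
                       per_sample_mean = preds,
                       extra = list(aggregate_R2 = r2(y, preds),
                                    aggregate_RMSE = rmse(y, preds)))
  list(train_r2 = r2(y, train_pred),
       cv_r2 = report$aggregate_R2,
       hyperparams = list(ntree = ntree, mtry = mtry,
                          nodesize = nodesize, seed = seed),
       report = report)
}

#' Recurrence of primary descriptors across discovered models
#'
#' For each primary descriptor referenced by any model, the fraction of
#' models whose term expressions reference it; descriptors never
#' referenced are absent from the table.
#'
#' @param models list of >= 2 `symbolic_model` objects.
#' @return A data.frame (`descriptor`, `recurrence`) sorted by
#'   decreasing recurrence (ties alphabetical).
#' @export
feature_recurrence <- function(models) {
  stopifnot(is.list(models), length(models) >= 2L)
  per_model <- lapply(models, function(m)
    unique(unlist(lapply(m$terms, function(t) expression_vars(t$expression)))))
  all_desc <- sort(unique(unlist(per_model)))
  frac <- vapply(all_desc, function(d)
    mean(vapply(per_model, function(v) d %in% v, logical(1))), numeric(1))
  out <- data.frame(descriptor = all_desc, recurrence = frac)
  out[order(-out$recurrence, out$descriptor), , drop = FALSE]
}
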