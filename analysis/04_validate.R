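#!/usr/bin/env Rscript

# Validation protocols over the discovered model: fixed-structure
# 5-fold CV, full-rerun repeated CV (the entire discovery pipeline
# re-run inside every fold across 5 seeds, per-sample mean
# predictions), the random-forest baseline under the same fold scheme,
# and feature recurrence across the full-rerun models.

suppressMessages(library(oemsol))
seed <- 2026L

tab <- utils::read.csv("results/synthetic_compounds.csv",
                       check.names = FALSE)
fm <- feature_matrix(as.matrix(tab[, !(names(tab) %in% c("id", "logS"))]),
                     row_ids = tab$id, target = tab$logS)
model <- read_symbolic_model("results/discovered_model.json")

fs <- fixed_structure_cv(model, fm, k = 5, seed = seed)
cat("fixed-structure 5-fold CV:\n"); print(fs)

fr <- full_rerun_cv(discover_config(), fm, k = 5, seeds = seed + 0:4)
cat("\nfull-rerun repeated CV:\n"); print(fr)

rf <- baseline_ensemble_cv(fm, k = 5, seed = seed)
cat(sprintf("\nrandom-forest baseline: train R^2 = %.3f, 5FCV R^2 = %.3f\n",
            rf$train_r2, rf$cv_r2))
cat(sprintf("overfitting gap: forest %.3f vs symbolic %.3f\n",
            rf$train_r2 - rf$cv_r2, model$r_squared - fs$mean_R2))

cat("\nfeature recurrence across full-rerun models:\n")
print(feature_recurrence(fr$models))

out <- data.frame(
  quantity = c("training_r2", "fixed_structure_cv_mean_r2",
               "fixed_structure_cv_mean_rmse", "full_rerun_r2",
               "full_rerun_rmse", "rf_train_r2", "rf_cv_r2"),
  value = c(model$r_squared, fs$mean_R2, fs$mean_RMSE,
            fr$aggregate_R2, fr$aggregate_RMSE, rf$train_r2, rf$cv_r2))
utils::write.csv(out, "results/validation.csv", row.names = FALSE)
cat("wrote results/validation.csv\n")
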