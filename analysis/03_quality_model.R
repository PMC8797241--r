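#!/usr/bin/env Rscript
# Step 3: model which processing choices drive network Quality.
#
# Quality is regressed on log10 sample count, log10 batch count, species,
# normalization (baseline Quantile), correction (baseline none) and
# correlation measure (baseline Pearson) over the training 75% of datasets,
# with 4-fold cross-validation for coefficient-sign stability, a workflow
# ranking, and each coefficient converted to its equivalent percent change
# in sample count.
#
# Outputs: results/model_coefficients.tsv, results/cv_coefficients.tsv,
# results/workflow_ranking.tsv, results/train_validation_split.tsv.

library(coexqc)

qt <- read.delim("results/quality_table.tsv")
info <- unique(qt[, c("dataset_id", "species")])
split <- split_train_validation(info, 0.75, seed = 7)
train <- qt[qt$dataset_id %in% split$train, ]

qm <- fit_quality_model(train)
co <- qm$coefficients
beta_n <- co$estimate[co$term == "log10_samples"]
# the conversion to an equivalent sample-count change extrapolates the
# fitted log-linear trend; report it only within two decades (|beta/beta_n|
# <= 2), beyond which the number is not interpretable
convertible <- !(co$term %in% c("(Intercept)", "log10_samples")) &
  abs(co$estimate / beta_n) <= 2
co$equiv_sample_change_pct <- ifelse(
  convertible, round(equivalent_sample_change(co$estimate, beta_n), 1), NA)
write.table(co, "results/model_coefficients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cv <- cross_validate(train, n_folds = 4, seed = 7)
cv_tab <- data.frame(term = rownames(cv$coefficients),
                     round(cv$coefficients, 4),
                     sign_consistent = cv$sign_consistent)
names(cv_tab)[2:5] <- paste0("fold", 1:4)
write.table(cv_tab, "results/cv_coefficients.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rk <- rank_workflows(train)
write.table(rk, "results/workflow_ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(
  data.frame(dataset_id = c(split$train, split$validation),
             role = rep(c("train", "validation"),
                        c(length(split$train), length(split$validation)))),
  "results/train_validation_split.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf("Model on %d training networks: R^2 = %.2f, df = %d.\n",
            qm$n_obs, qm$r_squared, qm$df_residual))
combat_beta <- co$estimate[co$term == "correctioncombat"]
combat_pct <- co$equiv_sample_change_pct[co$term == "correctioncombat"]
cat(sprintf(
  "Sample-count slope %.3f; EB correction adds %.3f Quality%s.\n",
  beta_n, combat_beta,
  if (is.na(combat_pct))
    " (beyond the range where an equivalent sample count is meaningful)"
  else sprintf(" (= %.0f%% more samples)", combat_pct)))
cat(sprintf("Coefficient signs consistent across all 4 folds: %d of %d terms.\n",
            sum(cv$sign_consistent), length(cv$sign_consistent)))
cat("Top-ranked workflow:", rk$workflow[1],
    sprintf("(above average in %d/%d datasets)\n", rk$n_above_average[1],
            rk$n_datasets[1]))
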