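#!/usr/bin/env Rscript
# Step 4: compare a default workflow against the optimized rule on the
# held-out validation datasets.
#
# Default: Rlog + no correction + Pearson. Optimized: UQ + EB correction,
# with Spearman correlation for datasets under 30 samples and Pearson
# otherwise. For each of the eight quality measures a one-sided paired
# t-test asks whether the optimized rule improves on the default.
#
# Output: results/default_vs_optimized.tsv.

library(coexqc)

measures <- read.delim("results/network_measures.tsv")
split <- read.delim("results/train_validation_split.tsv")
validation <- split$dataset_id[split$role == "validation"]

res <- compare_workflows_paired(measures, validation,
                                default = list(normalization = "Rlog",
                                               correction = "none",
                                               correlation = "pearson"),
                                optimized = list(normalization = "UQ",
                                                 correction = "combat"),
                                small_threshold = 30)
write.table(res, "results/default_vs_optimized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Validation datasets: %d.\n", length(validation)))
cat(sprintf(
  "Optimized beats default in %d-%d of them per measure; %d of 8 one-sided p-values < 0.05.\n",
  min(res$n_improved), max(res$n_improved), sum(res$p_value < 0.05)))
print(cbind(res[, c("measure", "mean_difference")],
            p_value = signif(res$p_value, 3)), row.names = FALSE)
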