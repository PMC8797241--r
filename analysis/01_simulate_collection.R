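#!/usr/bin/env Rscript
# Step 1: simulate a collection of multi-batch RNA-seq count datasets with
# known co-expression modules, batch effects and matched annotation sets.
#
# The collection emulates the shape of a public-compendium study: one
# dataset per cell type, sample counts spanning an order of magnitude,
# batch counts growing with sample counts, and per-gene per-batch shifts of
# sd 1 on the log2 scale. Two arbitrary species labels are assigned so the
# downstream regression exercises its species covariate.
#
# Outputs: scratch/collection/ (datasets + annotations, for steps 2-4) and
# results/collection_summary.tsv.

library(coexqc)

dir.create("scratch/collection", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

n_samples <- c(20, 28, 40, 56, 80, 110, 150, 210,
               24, 34, 48, 66, 95, 130, 180, 260)
n_batches <- pmax(2L, round(n_samples / 25))
species <- rep(c("speciesA", "speciesB"), each = 8)

summary_rows <- list()
for (d in seq_along(n_samples)) {
  cfg <- sim_config(n_genes = 800, n_samples = n_samples[d],
                    n_batches = n_batches[d], n_modules = 16,
                    module_size = 25, n_terms_per_domain = 30,
                    batch_loc_sd = 1, seed = 5000 + d)
  sim <- generate_dataset(cfg)
  ann <- generate_annotations(cfg, sim$truth)
  saveRDS(list(sim = sim, ann = ann, species = species[d]),
          sprintf("scratch/collection/dataset_%02d.rds", d))
  summary_rows[[d]] <- data.frame(
    dataset_id = sprintf("d%02d", d), species = species[d],
    n_genes = cfg$n_genes, n_samples = cfg$n_samples,
    n_batches = cfg$n_batches,
    n_module_genes = sum(!is.na(sim$truth$module_of_gene)))
}
summary <- do.call(rbind, summary_rows)
write.table(summary, "results/collection_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d datasets (%d-%d samples, %d-%d batches) into scratch/collection/.\n",
  nrow(summary), min(summary$n_samples), max(summary$n_samples),
  min(summary$n_batches), max(summary$n_batches)))
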