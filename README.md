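# coexqc

Benchmarking data-processing workflows for gene co-expression networks
built from multi-study RNA-seq count collections.

## The problem

Co-expression analysis — predicting gene function and regulation from which
genes rise and fall together — needs far more RNA-seq samples than any
single study provides, so in practice counts are pooled across many studies.
Every processing decision made on that pool changes the resulting networks:
the between-sample normalization, whether study-specific (batch) effects
are removed and how, and whether Pearson or Spearman correlation is used.
`coexqc` is for computational biologists who want to quantify those effects
systematically rather than pick a pipeline by convention.

A *workflow* is a triple (normalization, batch correction, correlation).
For each dataset (one cell type or tissue whose samples come from several
studies) and each workflow the package:

1. filters lowly expressed genes and normalizes the counts (TMM, CPM,
   upper-quartile, median, a simplified regularized log, or quantile
   normalization), then log2-transforms with a pooled 1st-percentile
   pseudocount;
2. removes batch effects within confounding blocks (connected components
   of the batch–biology graph), by per-gene linear removal or by
   parametric empirical-Bayes location-scale adjustment;
3. computes the gene–gene correlation matrix and, for every gene *X*, the
   set of its K = 100 most correlated genes (*set_X*);
4. scores the network with eight measures — for each annotation domain
   (GO-MF, GO-BP, GO-CC, TFBS motifs), the fraction of genes whose set_X
   has a significantly enriched term (*Enrichment*) and the fraction whose
   own annotations match those enriched terms (*Accuracy*), via one-sided
   hypergeometric tests with Benjamini–Hochberg control.

Across a network collection the eight standardized measures are collapsed
onto their first principal component and min–max rescaled to a single
**Quality** score in [0, 1]. A linear model then attributes Quality to
log10 sample count, log10 batch count, species, and the workflow
components; since Quality is linear in log10 samples with slope β_n, any
coefficient β converts to an equivalent sample-count change of
`100·(10^(β/β_n) − 1)` percent.

A negative-binomial synthetic-data generator with known co-expression
modules, batch effects, and matched annotation sets provides ground truth
for every stage.

## A worked example

Simulate a 500-gene, 80-sample dataset spread over 4 batches with strong
batch effects, and compare the same workflow with and without
empirical-Bayes batch correction:

```r
library(coexqc)
cfg <- sim_config(n_genes = 500, n_samples = 80, n_batches = 4,
                  n_modules = 10, module_size = 25, batch_loc_sd = 1,
                  n_terms_per_domain = 20, seed = 42)
sim <- generate_dataset(cfg)
ann <- generate_annotations(cfg, sim$truth)
net_raw <- build_network(sim$dataset, "UQ", "none",   "pearson", k = 100)
net_cor <- build_network(sim$dataset, "UQ", "combat", "pearson", k = 100)
rbind(uncorrected = unlist(network_quality_measures(net_raw, ann)[1, 1:8]),
      corrected   = unlist(network_quality_measures(net_cor, ann)[1, 1:8]))
#>             enrichment_mf enrichment_bp enrichment_cc enrichment_tfbs
#> uncorrected     0.4710744     0.4752066     0.4855372       0.4669421
#> corrected       0.7871901     0.7789256     0.7851240       0.7768595
#>             accuracy_mf accuracy_bp accuracy_cc accuracy_tfbs
#> uncorrected   0.3574380   0.3657025   0.3429752     0.3347107
#> corrected     0.3966942   0.4028926   0.3801653     0.3760331
```

With batch effects of sd 1 on the log2 scale, correcting them raises the
fraction of genes with a coherently annotated neighborhood from about 0.47
to about 0.78 in every domain — the network recovers the planted modules
far better from the same samples.

The equivalent-sample-count conversion, applied to the shipped reference
coefficients from a compendium-scale Quality regression (3,888 networks,
β_n = 0.2894):

```r
ref <- reference_model_coefficients()
beta_n <- ref$estimate[ref$term == "log10_samples"]
round(equivalent_sample_change(ref$estimate[ref$term == "UQ"], beta_n))
#> [1] 86
```

i.e. choosing upper-quartile normalization over quantile normalization is
worth as much as an 86% increase in sample count.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on a simulated
collection and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_collection.R` | 16 datasets (20–260 samples, 2–10 batches) with ground truth |
| `02_run_workflow_grid.R` | 12-workflow grid → 192 scored networks + Quality |
| `03_quality_model.R` | Quality regression, 4-fold CV, workflow ranking |
| `04_default_vs_optimized.R` | paired tests, default vs optimized rule, validation datasets |

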