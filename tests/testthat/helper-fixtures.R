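# small deterministic fixtures shared across test files

tiny_counts <- function(n_genes = 8, n_samples = 6, seed = 1, mu = 40) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 5),
                n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  })
}

tiny_dataset <- function(n_genes = 8, n_samples = 6, n_batches = 2,
                         seed = 1, mu = 40, biology = "bio1") {
  counts <- tiny_counts(n_genes, n_samples, seed, mu)
  samples <- data.frame(
    sample_id = colnames(counts),
    batch_id = paste0("batch", ((seq_len(n_samples) - 1) %% n_batches) + 1),
    biology_id = rep_len(biology, n_samples))
  count_dataset(counts, samples)
}

log_expr <- function(values, provenance = "normalize:CPM") {
  coexqc:::expr_matrix(values, provenance = provenance, log_scale = TRUE)
}

# hand-built modular network: genes grouped in blocks of (k+1); each gene's
# neighbors are exactly the other members of its block, then background
block_network <- function(n_blocks = 4, block_size = 6, n_background = 6,
                          k = block_size - 1) {
  n <- n_blocks * block_size + n_background
  ids <- sprintf("g%03d", seq_len(n))
  cm <- matrix(0.05, n, n, dimnames = list(ids, ids))
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1) * block_size + seq_len(block_size)
    cm[idx, idx] <- 0.9
  }
  if (n_background > 0) {
    # background genes form their own unannotated correlated block so their
    # neighbor sets stay free of annotated genes
    idx <- n_blocks * block_size + seq_len(n_background)
    cm[idx, idx] <- 0.9
  }
  diag(cm) <- 1
  top_k_neighbors(cm, k = k)
}

block_annotations <- function(n_blocks = 4, block_size = 6,
                              n_background = 6) {
  n <- n_blocks * block_size + n_background
  ids <- sprintf("g%03d", seq_len(n))
  ann <- lapply(c(MF = "MF", BP = "BP", CC = "CC", TFBS = "TFBS"),
                function(d) {
    sets <- lapply(seq_len(n_blocks), function(b)
      ids[(b - 1) * block_size + seq_len(block_size)])
    names(sets) <- sprintf("%s_T%02d", d, seq_len(n_blocks))
    sets
  })
  ann
}

random_measures <- function(n, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    m <- sapply(quality_measure_columns(), function(x)
      pmin(pmax(0.5 + 0.15 * f + rnorm(n, 0, 0.05), 0), 1))
    as.data.frame(m)
  })
}
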