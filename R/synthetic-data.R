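#' Configuration for the synthetic count-data generator
#'
#' Describes one simulated multi-batch RNA-seq dataset for a single cell type
#' or tissue: negative-binomial counts with variable library sizes, latent
#' co-expression modules shared by annotated gene sets, and per-batch
#' location and scale effects.
#'
#' The generative model on the log2 scale is
#' `log2 mean = b_g + L * a_{m(g),s} + gamma_{g,b(s)} + e_{g,s}` where
#' `a_{m,s} ~ N(0,1)` is the activity of module `m` in sample `s`,
#' `b_g ~ N(baseline_log_mean, baseline_log_sd)` a per-gene intercept,
#' `gamma_{g,b} ~ N(0, batch_loc_sd)` a per-gene per-batch shift and
#' `e_{g,s} ~ N(0, sd = 0.5 * exp(delta_b / 2))` residual noise whose base
#' variance 0.25 is inflated per batch by `exp(delta_b)`,
#' `delta_b ~ N(0, batch_scale_sd)`. Counts are drawn as
#' `NB(mean = l_s * 2^log2mean, dispersion phi)` with
#' `variance = mu + phi * mu^2` and log-normal library factor
#' `l_s` (`log sd = libsize_log_sd`).
#'
#' @param n_genes,n_samples,n_batches Dimensions of the dataset. Samples are
#'   assigned to batches round-robin, so batches are balanced.
#' @param n_modules,module_size Number of ground-truth co-expression modules
#'   and genes per module (`n_modules * module_size <= n_genes`).
#' @param loading Module effect size `L` on the log2 scale; with the base
#'   residual variance of 0.25 the within-module correlation of the latent
#'   log-expression is `L^2 / (L^2 + 0.25)`.
#' @param baseline_log_mean,baseline_log_sd Mean and sd of per-gene log2
#'   expression intercepts.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (`variance = mu + phi * mu^2`); values near 0 approach Poisson noise.
#' @param batch_loc_sd Sd of per-gene per-batch log2 shifts (additive batch
#'   effect).
#' @param batch_scale_sd Sd of `delta_b`, the per-batch log multiplicative
#'   inflation of the residual noise variance (scale batch effect).
#' @param libsize_log_sd Log sd of the per-sample library-size factor.
#' @param n_terms_per_domain Annotation terms per domain; must be at least
#'   `n_modules` (one term per module, the rest are background terms).
#' @param annot_tpr Probability that a module gene carries its module's term.
#' @param annot_fpr Probability that any gene carries any given background
#'   term.
#' @param outlier_samples,outlier_log_sd Optional heavy-tailed
#'   contamination: `outlier_samples` whole samples (e.g. degraded
#'   libraries) receive independent per-gene `N(0, outlier_log_sd)` shocks
#'   on the log2 mean. Default off. The count is fixed rather than a rate:
#'   a couple of corrupted libraries occur regardless of dataset size, so
#'   their leverage on correlation estimates shrinks as samples accumulate
#'   - the mechanism by which extreme values penalize Pearson correlation
#'   in small datasets.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_samples = 100, n_batches = 5,
                       n_modules = 20, module_size = 25, loading = 1,
                       baseline_log_mean = 5, baseline_log_sd = 1.5,
                       nb_dispersion = 0.1, batch_loc_sd = 1,
                       batch_scale_sd = 0.25, libsize_log_sd = 0.3,
                       n_terms_per_domain = 30, annot_tpr = 0.8,
                       annot_fpr = 0.02, outlier_samples = 0L,
                       outlier_log_sd = 2, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_batches = as.integer(n_batches), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size), loading = loading,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, nb_dispersion = nb_dispersion,
              batch_loc_sd = batch_loc_sd, batch_scale_sd = batch_scale_sd,
              libsize_log_sd = libsize_log_sd,
              n_terms_per_domain = as.integer(n_terms_per_domain),
              annot_tpr = annot_tpr, annot_fpr = annot_fpr,
              outlier_samples = as.integer(outlier_samples),
              outlier_log_sd = outlier_log_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_samples > 0, n_batches > 0, n_modules > 0,
              module_size > 0, loading >= 0, baseline_log_sd >= 0,
              nb_dispersion > 0, batch_loc_sd >= 0, batch_scale_sd >= 0,
              libsize_log_sd >= 0, n_terms_per_domain > 0,
              outlier_samples >= 0, outlier_log_sd >= 0)
    if (n_modules * module_size > n_genes)
      stop("n_modules * module_size must not exceed n_genes")
    if (annot_tpr < 0 || annot_tpr > 1 || annot_fpr < 0 || annot_fpr > 1)
      stop("annotation probabilities must be in [0, 1]")
    if (n_batches > n_samples)
      stop("n_batches must not exceed n_samples")
    if (n_terms_per_domain < n_modules)
      stop("n_terms_per_domain must be at least n_modules")
  })
  structure(cfg, class = "sim_config")
}

annotation_domains <- function() c("MF", "BP", "CC", "TFBS")

#' Generate a synthetic count dataset with known module structure
#'
#' Draws one dataset from the model described in [sim_config()] and returns
#' it together with the ground truth (which gene belongs to which module,
#' and which annotation term each module carries in each domain).
#'
#' @param config A [sim_config()].
#' @param confounded_biology If `TRUE`, each batch is wholly assigned one of
#'   two biology labels (batch confounded with biology), for exercising the
#'   confounding partitioner. Default: a single biology label, as in
#'   per-cell-type network construction.
#' @return A list with elements `dataset` (a [count_dataset()]) and `truth`
#'   (list with `module_of_gene`, an integer vector with `NA` for
#'   non-module genes, and `term_of_module`, a per-domain list of term ids).
#' @export
generate_dataset <- function(config, confounded_biology = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  c2 <- config
  withr::with_seed(c2$seed, {
    G <- c2$n_genes; S <- c2$n_samples; B <- c2$n_batches; M <- c2$n_modules
    gene_ids <- sprintf("g%05d", seq_len(G))
    sample_ids <- sprintf("s%04d", seq_len(S))
    batch <- ((seq_len(S) - 1L) %% B) + 1L
    module_of_gene <- rep(NA_integer_, G)
    module_of_gene[seq_len(M * c2$module_size)] <-
      rep(seq_len(M), each = c2$module_size)
    names(module_of_gene) <- gene_ids

    a <- matrix(stats::rnorm(M * S), M, S)                  # module activities
    b <- stats::rnorm(G, c2$baseline_log_mean, c2$baseline_log_sd)
    gamma <- matrix(stats::rnorm(G * B, 0, c2$batch_loc_sd), G, B)
    delta <- stats::rnorm(B, 0, c2$batch_scale_sd)
    resid_sd <- 0.5 * exp(delta / 2)                        # variance 0.25*exp(delta)

    log2mean <- matrix(b, G, S)
    in_mod <- !is.na(module_of_gene)
    log2mean[in_mod, ] <- log2mean[in_mod, ] +
      c2$loading * a[module_of_gene[in_mod], , drop = FALSE]
    log2mean <- log2mean + gamma[, batch, drop = FALSE]
    e <- matrix(stats::rnorm(G * S, 0, rep(resid_sd[batch], each = G)), G, S)
    log2mean <- log2mean + e
    if (c2$outlier_samples > 0) {
      bad <- sample(S, min(c2$outlier_samples, S))
      log2mean[, bad] <- log2mean[, bad] +
        matrix(stats::rnorm(G * length(bad), 0, c2$outlier_log_sd),
               G, length(bad))
    }

    libfac <- exp(stats::rnorm(S, 0, c2$libsize_log_sd))
    mu <- sweep(2^log2mean, 2, libfac, `*`)
    counts <- matrix(
      stats::rnbinom(G * S, mu = as.vector(mu), size = 1 / c2$nb_dispersion),
      G, S, dimnames = list(gene_ids, sample_ids))

    biology <- if (confounded_biology) {
      paste0("bio", ifelse(batch <= ceiling(B / 2), 1L, 2L))
    } else rep("bio1", S)
    samples <- data.frame(sample_id = sample_ids,
                          batch_id = paste0("batch", batch),
                          biology_id = biology)
    term_of_module <- lapply(annotation_domains(), function(d)
      sprintf("%s_T%03d", d, seq_len(M)))
    names(term_of_module) <- annotation_domains()
    list(dataset = count_dataset(counts, samples),
         truth = list(module_of_gene = module_of_gene,
                      term_of_module = term_of_module))
  })
}

#' Generate annotation gene sets matched to the simulated modules
#'
#' For each of the four annotation domains (GO-MF, GO-BP, GO-CC, TFBS) a
#' term-to-genes map is produced: each module's term receives each of the
#' module's genes with probability `annot_tpr`, and every gene receives each
#' background term with probability `annot_fpr`. The result is serializable
#' as GMT via [write_gmt()].
#'
#' @param config The [sim_config()] used for [generate_dataset()].
#' @param truth The `truth` element returned by [generate_dataset()].
#' @return Named list over domains; each domain is a named list
#'   term -> character vector of gene ids.
#' @export
generate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- names(truth$module_of_gene)
  withr::with_seed(config$seed + 1000003L, {
    out <- lapply(annotation_domains(), function(d) {
      terms <- vector("list", config$n_terms_per_domain)
      mod_terms <- truth$term_of_module[[d]]
      n_bg <- config$n_terms_per_domain - config$n_modules
      names(terms) <- c(mod_terms,
                        if (n_bg > 0) sprintf("%s_BG%03d", d, seq_len(n_bg)))
      for (m in seq_len(config$n_modules)) {
        members <- gene_ids[!is.na(truth$module_of_gene) &
                              truth$module_of_gene == m]
        keep <- stats::runif(length(members)) < config$annot_tpr
        terms[[mod_terms[m]]] <- members[keep]
      }
      if (n_bg > 0) {
        for (i in seq_len(n_bg)) {
          keep <- stats::runif(length(gene_ids)) < config$annot_fpr
          terms[[config$n_modules + i]] <- gene_ids[keep]
        }
      }
      terms
    })
    names(out) <- annotation_domains()
    out
  })
}

#' Write a simulated dataset, annotations and ground truth to a directory
#'
#' Writes `counts.tsv`, `meta.tsv`, one `annotations_<domain>.gmt` per
#' domain, and `truth.json`.
#'
#' @param sim Result of [generate_dataset()].
#' @param annots Result of [generate_annotations()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, annots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_dataset(sim$dataset, file.path(dir, "counts.tsv"),
                      file.path(dir, "meta.tsv"))
  for (d in names(annots))
    write_gmt(annots[[d]], file.path(dir, sprintf("annotations_%s.gmt", d)))
  jsonlite::write_json(
    list(module_of_gene = as.list(sim$truth$module_of_gene),
         term_of_module = sim$truth$term_of_module),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}
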