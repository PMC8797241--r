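#' Enumerate the benchmarked workflow grid
#'
#' The full design crosses 6 normalizations with 4 batch-correction options
#' (none, linear removal, EB location-scale adjustment, and a count-based
#' NB-regression correction applied instead of normalization), times 2
#' correlation measures: (6 x 4 + 1) x 2 = 50 workflows. The count-based
#' correction (`combatseq`) is enumerable but not executable by this
#' package; the executable subset is 6 x 3 x 2 = 36 workflows.
#'
#' @param executable_only If `TRUE`, return only the 36 executable
#'   workflows.
#' @return Data frame with columns `normalization`, `correction`,
#'   `correlation` and `executable`.
#' @export
enumerate_workflow_design <- function(executable_only = FALSE) {
  norms <- c("TMM", "CPM", "UQ", "Med", "Rlog", "Quantile")
  full <- expand.grid(normalization = norms,
                      correction = c("none", "linear", "combat", "combatseq"),
                      correlation = c("pearson", "spearman"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # the count-based correction replaces normalization rather than following it
  full <- full[full$correction != "combatseq", ]
  extra <- expand.grid(normalization = "none", correction = "combatseq",
                       correlation = c("pearson", "spearman"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  csq <- expand.grid(normalization = norms, correction = "combatseq",
                     correlation = c("pearson", "spearman"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- rbind(full, csq, extra)
  design$executable <- design$correction != "combatseq"
  rownames(design) <- NULL
  if (executable_only) design[design$executable, , drop = FALSE] else design
}

workflow_label <- function(normalization, correction, correlation) {
  paste(normalization, correction, correlation, sep = "+")
}

#' Run a workflow grid over a dataset collection
#'
#' For every dataset x workflow combination the full pipeline is executed
#' (filter, normalize, log, correct, correlate, top-K) and the eight quality
#' measures are computed; one row per network is returned together with
#' dataset covariates (sample count, batch count, species). Failures of
#' individual networks are caught, logged as attribute `"failures"` and
#' recorded as missing rows rather than aborting the grid. Finally
#' [combine_quality()] is applied over all complete rows.
#'
#' @param datasets Named list of [count_dataset()] objects (names are
#'   dataset ids).
#' @param specs Data frame of workflows as from [enumerate_workflow_design()]
#'   (only executable rows are run).
#' @param annots_list Either one annotation list (shared by all datasets) or
#'   a named list of per-dataset annotation lists.
#' @param k Neighbors per gene.
#' @param alpha Enrichment significance threshold.
#' @param species Optional named character vector dataset id -> species
#'   label (default `"synthetic"`).
#' @param min_term_size Minimum tested term size.
#' @return List with `measures` (one row per network), `quality` (a
#'   `quality_score_table` over the complete rows) and `failures`
#'   (data frame of failed networks, possibly empty).
#' @export
run_workflow_grid <- function(datasets, specs, annots_list, k = 100,
                              alpha = 0.05, species = NULL,
                              min_term_size = 5) {
  stopifnot(length(datasets) > 0, !is.null(names(datasets)))
  specs <- as.data.frame(specs)
  if ("executable" %in% names(specs))
    specs <- specs[specs$executable, , drop = FALSE]
  per_dataset <- !is.null(names(annots_list)) &&
    all(names(datasets) %in% names(annots_list))
  rows <- list()
  failures <- list()
  for (id in names(datasets)) {
    data <- datasets[[id]]
    annots <- if (per_dataset) annots_list[[id]] else annots_list
    sp <- if (!is.null(species)) species[[id]] else "synthetic"
    covar <- data.frame(
      dataset_id = id,
      n_samples = ncol(data$counts),
      n_batches = length(unique(data$samples$batch_id)),
      species = sp)
    keep <- filter_genes(data)
    sub <- count_dataset(data$counts[keep, , drop = FALSE], data$samples)
    for (nm in unique(specs$normalization)) {
      expr0 <- tryCatch({
        e <- normalize_counts(sub, nm)
        if (!e$log_scale) e <- log_transform(e)
        e
      }, error = function(err) err)
      for (cr in unique(specs$correction[specs$normalization == nm])) {
        corrected <- if (inherits(expr0, "error")) expr0 else
          tryCatch(correct_batch(expr0, sub$samples, cr),
                   error = function(err) err)
        cors <- specs$correlation[specs$normalization == nm &
                                    specs$correction == cr]
        for (cc in cors) {
          lbl <- workflow_label(nm, cr, cc)
          row <- tryCatch({
            if (inherits(corrected, "error")) stop(corrected)
            sds <- apply(corrected$values, 1, stats::sd)
            values <- corrected$values[sds > 0, , drop = FALSE]
            cm <- correlation_matrix(values, cc)
            net <- top_k_neighbors(cm, k = min(k, nrow(cm) - 1), method = cc)
            meas <- network_quality_measures(net, annots, alpha = alpha,
                                             min_term_size = min_term_size)
            cbind(covar, normalization = nm, correction = cr,
                  correlation = cc, workflow = lbl, meas)
          }, error = function(err) err)
          if (inherits(row, "error")) {
            failures[[length(failures) + 1L]] <- data.frame(
              dataset_id = id, workflow = lbl,
              error = conditionMessage(row))
          } else {
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  }
  measures <- do.call(rbind, rows)
  fail_df <- if (length(failures)) do.call(rbind, failures) else
    data.frame(dataset_id = character(0), workflow = character(0),
               error = character(0))
  quality <- if (!is.null(measures) && nrow(measures) >= 3)
    combine_quality(measures) else NULL
  list(measures = measures, quality = quality, failures = fail_df)
}

#' Split dataset ids into training and validation sets
#'
#' Random split stratified by species: within each species,
#' `floor(fraction * n)` ids are drawn for training and the rest form the
#' validation set. Deterministic given the seed; the partition is exact
#' (disjoint and exhaustive).
#'
#' @param dataset_info Data frame with columns `dataset_id` and `species`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `validation`.
#' @export
split_train_validation <- function(dataset_info, fraction = 0.75, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  withr::with_seed(seed, {
    train <- unlist(lapply(split(dataset_info$dataset_id,
                                 dataset_info$species), function(ids) {
      n_train <- max(1L, floor(fraction * length(ids)))
      sample(ids, n_train)
    }), use.names = FALSE)
    list(train = sort(train),
         validation = sort(setdiff(dataset_info$dataset_id, train)))
  })
}

#' Fit the Quality regression model
#'
#' Ordinary least squares of Quality on log10 sample count, log10 batch
#' count, species, normalization, batch correction and correlation measure,
#' with 0/1 dummy coding and the stated baseline levels. Categorical
#' predictors with a single observed level are dropped from the model (they
#' carry no information in such a collection). Returns coefficient
#' estimates, standard errors, t values (estimate / SE) and two-sided
#' t-test p values with `df = n_obs - n_coefficients`.
#'
#' @param table Data frame with columns `quality`, `n_samples`,
#'   `n_batches`, `species`, `normalization`, `correction`, `correlation`
#'   (e.g. the `quality$table` of [run_workflow_grid()]).
#' @param baselines Named list of baseline levels for the dummy coding.
#' @return An object of class `quality_model`: list with `coefficients`
#'   (data frame: term, estimate, std_error, t_value, p_value),
#'   `r_squared`, `df_residual`, `n_obs` and the underlying `lm` fit.
#' @export
fit_quality_model <- function(table,
                              baselines = list(species = "human",
                                               normalization = "Quantile",
                                               correction = "none",
                                               correlation = "pearson")) {
  table <- as.data.frame(table)
  req <- c("quality", "n_samples", "n_batches", "species", "normalization",
           "correction", "correlation")
  stopifnot(all(req %in% names(table)))
  df <- data.frame(quality = table$quality,
                   log10_samples = log10(table$n_samples),
                   log10_batches = log10(table$n_batches))
  terms <- c("log10_samples", "log10_batches")
  for (v in c("species", "normalization", "correction", "correlation")) {
    f <- factor(table[[v]])
    if (nlevels(f) > 1) {
      if (baselines[[v]] %in% levels(f))
        f <- stats::relevel(f, baselines[[v]])
      df[[v]] <- f
      terms <- c(terms, v)
    }
  }
  if (stats::var(df$log10_batches) == 0)
    terms <- setdiff(terms, "log10_batches")
  n_coef_guess <- 1 + length(terms)
  if (nrow(df) < n_coef_guess + 1)
    stop("too few rows to fit the quality model")
  fml <- stats::as.formula(paste("quality ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              std_error = co[, 2], t_value = co[, 3],
                              p_value = co[, 4], row.names = NULL),
    r_squared = sm$r.squared,
    df_residual = fit$df.residual,
    n_obs = nrow(df),
    fit = fit), class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("quality_model: n = %d, df = %d, R^2 = %.3f\n",
              x$n_obs, x$df_residual, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Equivalent change in sample count for a model coefficient
#'
#' Because Quality is modeled as linear in log10 sample count with slope
#' `beta_n`, an additive Quality effect `beta` of any other predictor is
#' equivalent to multiplying the sample count by `10^(beta / beta_n)`. The
#' returned value is the corresponding percent change,
#' `100 * (10^(beta / beta_n) - 1)`; negative values are percent decreases.
#'
#' @param beta Coefficient (Quality units); vectorized.
#' @param beta_n Positive coefficient of log10 sample count.
#' @return Percent change in equivalent sample count.
#' @export
equivalent_sample_change <- function(beta, beta_n) {
  if (!is.numeric(beta_n) || length(beta_n) != 1 || beta_n <= 0)
    stop("beta_n must be a single positive number")
  100 * (10^(beta / beta_n) - 1)
}

#' Reference Quality-model coefficients from a large-scale compendium
#'
#' Coefficient estimates of the Quality regression fitted on 3,888
#' co-expression networks built from a public human/mouse RNA-seq
#' compendium (training networks of 108 cell types and tissues under the 36
#' executable workflows). Shipped as package data for worked examples and
#' for the equivalent-sample-count conversions; these numbers are inputs,
#' not outputs, of this package.
#'
#' @return Data frame with columns `group`, `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`.
#' @export
reference_model_coefficients <- function() {
  path <- system.file("extdata", "reference_quality_model.tsv",
                      package = "coexqc", mustWork = TRUE)
  utils::read.delim(path)
}

#' Cross-validate the Quality model by dataset folds
#'
#' Dataset ids (cell types/tissues), not network rows, are partitioned into
#' folds stratified by species; the model is refitted on each
#' leave-one-fold-out subset and the consistency of coefficient signs
#' across folds is reported.
#'
#' @param table As for [fit_quality_model()], plus a `dataset_id` column.
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed for the fold assignment.
#' @param baselines Passed to [fit_quality_model()].
#' @return List with `models` (per-fold `quality_model`s), `folds` (named
#'   fold assignment of dataset ids), `coefficients` (term x fold estimate
#'   matrix) and `sign_consistent` (logical per term).
#' @export
cross_validate <- function(table, n_folds = 4, seed = 1L,
                           baselines = list(species = "human",
                                            normalization = "Quantile",
                                            correction = "none",
                                            correlation = "pearson")) {
  table <- as.data.frame(table)
  info <- unique(table[, c("dataset_id", "species")])
  folds <- withr::with_seed(seed, {
    unlist(lapply(split(info$dataset_id, info$species), function(ids) {
      ids <- sample(ids)
      stats::setNames(rep_len(seq_len(n_folds), length(ids)), ids)
    }))
  })
  names(folds) <- sub("^[^.]*\\.", "", names(folds))
  models <- lapply(seq_len(n_folds), function(f) {
    held_out <- names(folds)[folds == f]
    fit_quality_model(table[!(table$dataset_id %in% held_out), , drop = FALSE],
                      baselines = baselines)
  })
  terms <- models[[1]]$coefficients$term
  est <- sapply(models, function(m)
    m$coefficients$estimate[match(terms, m$coefficients$term)])
  rownames(est) <- terms
  list(models = models, folds = folds, coefficients = est,
       sign_consistent = apply(est, 1, function(x)
         all(sign(x) == sign(x[1]))))
}

#' Rank workflows by average Quality
#'
#' Per workflow: the mean Quality across datasets and the number of
#' datasets in which the workflow's network exceeded that dataset's mean
#' Quality over all evaluated workflows ("above-average count"). Sorted by
#' mean Quality descending, ties broken by workflow label.
#'
#' @param quality_table Data frame with columns `dataset_id`,
#'   `normalization`, `correction`, `correlation` and `quality`.
#' @return Data frame: workflow, normalization, correction, correlation,
#'   mean_quality, n_above_average, n_datasets.
#' @export
rank_workflows <- function(quality_table) {
  qt <- as.data.frame(quality_table)
  stopifnot(nrow(qt) > 0)
  qt$workflow <- workflow_label(qt$normalization, qt$correction,
                                qt$correlation)
  if (length(unique(qt$workflow)) < 2) stop("need at least 2 workflows")
  ds_mean <- tapply(qt$quality, qt$dataset_id, mean)
  qt$above <- qt$quality > ds_mean[qt$dataset_id]
  agg <- do.call(rbind, lapply(split(qt, qt$workflow), function(g) {
    data.frame(workflow = g$workflow[1],
               normalization = g$normalization[1],
               correction = g$correction[1],
               correlation = g$correlation[1],
               mean_quality = mean(g$quality),
               n_above_average = sum(g$above),
               n_datasets = nrow(g))
  }))
  agg <- agg[order(-agg$mean_quality, agg$workflow), ]
  rownames(agg) <- NULL
  agg
}

#' Paired comparison of a default vs an optimized workflow
#'
#' On validation datasets, compares the eight raw quality measures between
#' a default workflow and an optimized rule that switches the correlation
#' measure by sample count (rank correlation below the threshold, linear
#' correlation otherwise). For each measure a one-sided paired t-test
#' (alternative: optimized > default) is reported together with the number
#' of datasets improved. With zero variance of the differences the t-test
#' is degenerate: the p value is reported as 0 if the common difference is
#' positive and 1 otherwise.
#'
#' @param measures Data frame of per-network measures as produced by
#'   [run_workflow_grid()] (`$measures`).
#' @param validation_ids Dataset ids to compare on.
#' @param default Named list with `normalization`, `correction`,
#'   `correlation` of the default workflow.
#' @param optimized Named list with `normalization`, `correction` of the
#'   optimized workflow (its correlation follows the sample-count rule).
#' @param small_threshold Sample count below which the optimized rule uses
#'   Spearman correlation (default 30).
#' @return Data frame with one row per measure: measure, mean_difference,
#'   t_statistic, p_value, n_improved, n_datasets.
#' @export
compare_workflows_paired <- function(measures, validation_ids,
                                     default = list(normalization = "Rlog",
                                                    correction = "none",
                                                    correlation = "pearson"),
                                     optimized = list(normalization = "UQ",
                                                      correction = "combat"),
                                     small_threshold = 30) {
  ms <- as.data.frame(measures)
  ms <- ms[ms$dataset_id %in% validation_ids, , drop = FALSE]
  pick <- function(id, nm, cr, cc) {
    row <- ms[ms$dataset_id == id & ms$normalization == nm &
                ms$correction == cr & ms$correlation == cc, , drop = FALSE]
    if (nrow(row) != 1)
      stop(sprintf("workflow %s missing for dataset '%s'",
                   workflow_label(nm, cr, cc), id))
    row
  }
  cols <- quality_measure_columns()
  diffs <- matrix(NA_real_, length(validation_ids), length(cols),
                  dimnames = list(validation_ids, cols))
  for (id in validation_ids) {
    def <- pick(id, default$normalization, default$correction,
                default$correlation)
    opt_cor <- if (def$n_samples < small_threshold) "spearman" else "pearson"
    opt <- pick(id, optimized$normalization, optimized$correction, opt_cor)
    diffs[id, ] <- as.numeric(opt[1, cols]) - as.numeric(def[1, cols])
  }
  if (nrow(diffs) < 3) stop("need at least 3 paired observations")
  do.call(rbind, lapply(cols, function(mcol) {
    d <- diffs[, mcol]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 p.value = if (mean(d) > 0) 0 else 1)
    } else {
      tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      tt <- list(statistic = tstat,
                 p.value = stats::pt(tstat, length(d) - 1,
                                     lower.tail = FALSE))
    }
    data.frame(measure = mcol, mean_difference = mean(d),
               t_statistic = tt$statistic, p_value = tt$p.value,
               n_improved = sum(d > 0), n_datasets = length(d))
  }))
}
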